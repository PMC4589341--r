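# build a cycle histogram object directly from a count vector
fake_hist <- function(counts, T0 = 10) {
  n <- length(counts)
  edges <- seq(-T0 / 2, T0 / 2, length.out = n + 1)
  structure(list(T0 = T0, bin_edges = edges,
                 bin_centers = (edges[-1] + edges[-(n + 1)]) / 2,
                 counts = as.integer(counts),
                 n_spikes_total = sum(counts)),
            class = "cycle_histogram")
}

test_that("a histogram proportional to the signal correlates perfectly at lag 0", {
  s <- signal_params(A = 0.3, f0 = 0.1)
  centers <- fake_hist(rep(0, 100))$bin_centers
  counts <- round(1000 + 500 * sin(2 * pi * s$f0 * centers))
  cr <- mutual_correlation(fake_hist(counts), s)
  expect_gt(cr$max_C, 0.999)
  expect_equal(cr$tau_at_max, 0)
  expect_true(all(abs(cr$C_values) <= 1 + 1e-12))
  expect_true(all(range(cr$tau_grid) == c(-5, 5)))
})

test_that("a narrow locked peak yields the crest-alignment delay", {
  # spikes locked at phase 2 with small jitter: correlation with
  # A sin(2 pi f0 t~) peaks when the crest (T0/4 = 2.5) aligns, tau = 0.5
  s <- signal_params(A = 0.3, f0 = 0.1)
  tr <- gen_locked_train(10, phase = 2, jitter_sd = 0.3, n_spikes = 3000,
                         seed = 3)
  cr <- mutual_correlation(cycle_histogram(tr$times, s), s)
  expect_lt(abs(cr$tau_at_max - 0.5), 0.2)
})

test_that("C(tau) is invariant to affine rescaling of the histogram", {
  s <- signal_params(A = 0.1, f0 = 0.1)
  counts <- withr::with_seed(2, rpois(100, 40))
  c1 <- mutual_correlation(fake_hist(counts), s)
  c2 <- mutual_correlation(fake_hist(3 * counts + 17), s)
  expect_equal(c1$C_values, c2$C_values, tolerance = 1e-12)
  expect_error(mutual_correlation(fake_hist(rep(5, 100)), s), "degenerate")
  expect_error(mutual_correlation(fake_hist(counts), s, tau_step = 0),
               "tau_step")
})

test_that("mutual information respects its bounds on arbitrary histograms", {
  s <- signal_params(A = 0.3, f0 = 0.1)
  withr::with_seed(7, {
    for (i in 1:8) {
      counts <- rpois(100, sample(c(2, 20, 200), 1))
      mi <- mutual_information(fake_hist(counts), s)
      expect_gte(mi$MI, 0)
      expect_lte(mi$MI, mi$H_F + 1e-12)
      expect_lte(mi$MI, log2(20) + 1e-12)
      expect_equal(mi$m_s, 20L)
      expect_lte(mi$m_f, 20L)
    }
  })
})

test_that("degenerate and deterministic histograms give MI = 0 and MI = H(F)", {
  s <- signal_params(A = 0.3, f0 = 0.1)
  # constant counts: H(F) = 0, MI = 0
  mi0 <- mutual_information(fake_hist(rep(7, 100)), s)
  expect_equal(mi0$MI, 0)
  expect_equal(mi0$H_F, 0)
  # all-zero histogram: MI = 0 by convention
  miz <- mutual_information(fake_hist(rep(0, 100)), s)
  expect_equal(miz$MI, 0)

  # counts a deterministic, state-distinct function of the signal state:
  # H(F|S) = 0, so MI = H(F)
  h <- fake_hist(rep(0, 100))
  sig <- s$A * sin(2 * pi * s$f0 * h$bin_centers)
  s_state <- floor((sig + s$A) / (2 * s$A) * 20) + 1
  s_state <- pmin(pmax(s_state, 1), 20)
  mi <- mutual_information(fake_hist(s_state), s)
  expect_equal(mi$H_F_given_S, 0, tolerance = 1e-12)
  expect_equal(mi$MI, mi$H_F)
  expect_gt(mi$MI, 2)
})

test_that("phase-uniform trains carry no signal information (finely binned)", {
  s <- signal_params(A = 0.3, f0 = 0.1)
  tr <- gen_uniform_train(10, rate = 1, duration = 1e5, seed = 7)
  h <- cycle_histogram(tr$times, s, n_bins = 2000)
  # null correlation: sd ~ 1/sqrt(n_bins)
  cr <- mutual_correlation(h, s)
  expect_lt(max(abs(cr$C_values)), 0.05)
  # independence baseline: MI below 0.1 bits once the plug-in bias
  # (m_s-1)(m_f-1)/(2 n_bins ln 2) is small
  mi <- mutual_information(h, s)
  expect_lt(mi$MI, 0.1)
})

test_that("the sensitivity map flags the threshold and prompt points", {
  sm <- sensitivity_map(c(-16, -11), c(0.3), duration_ms = 6000,
                        n_blocks = 25, cfg = cfg_fast())
  expect_equal(nrow(sm), 2)
  expect_true(all(sm$ok))
  # chaotic at -16, not at -11: the threshold flag sits at d = -16
  expect_true(sm$d_thr[sm$d == -16])
  expect_false(sm$d_thr[sm$d == -11])
  expect_identical(sm$prompt, !is.na(sm$max_C) & sm$max_C > 0.8 &
                     abs(sm$tau_at_max) < 1.5)
  expect_error(sensitivity_map(numeric(0), 1), "non-empty")
})
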