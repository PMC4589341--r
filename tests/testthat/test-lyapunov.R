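test_that("saltation matrix has the reset structure and matches direct arithmetic", {
  p <- p_chaotic()
  lr <- lyapunov_spectrum(p, cfg = cfg_fast(), n_blocks = 10)
  for (i in seq_len(min(25, nrow(lr$spikes)))) {
    ev <- lr$spikes[i, ]
    S <- saltation_matrix(ev, p)
    # structural zeros of the reset jump
    expect_identical(S[1, 2], 0)
    expect_identical(S[2, 2], 1)
    # independent re-evaluation from the flow components
    fm <- izh_flow(izh_state(ev$t_spike, 30, ev$u_pre), p)
    fp <- izh_flow(izh_state(ev$t_spike, p$c, ev$u_pre + p$d), p)
    expect_equal(S[1, 1], unname(fp[1] / fm[1]))
    expect_equal(S[2, 1], unname((fp[2] - fm[2]) / fm[1]))
  }
})

test_that("generic saltation reduces to the identity for a continuous flow", {
  f <- c(3.2, -0.7)
  S <- saltation_general(f, f, Dg = matrix(c(0, 0, 0, 1), 2, 2), n = c(1, 0))
  expect_equal(S, diag(2))
  expect_error(saltation_general(c(0, 1), c(0, 1), diag(2), c(1, 0)),
               "tangential")
})

test_that("spectrum of linear hybrid systems matches closed forms", {
  # contracting flow, no events: exponents are the eigenvalue real parts
  sys <- make_linear_hybrid(c(-0.3, -1.2))
  lh <- lyapunov_spectrum_hybrid(sys, c(0.5, 0.5), t_total = 60, block_ms = 10)
  expect_lt(max(abs(lh$lambda - c(-0.3, -1.2)) / c(0.3, 1.2)), 0.02)

  # sawtooth flow with a contracting jump: monodromy diag(1, s e^m) per
  # unit period, spectrum (0, m + log s); incommensurate block length so
  # no event sits exactly on a block boundary
  sw <- make_sawtooth_hybrid(m = -0.5, s = 0.8)
  lh2 <- lyapunov_spectrum_hybrid(sw, c(0, 1), t_total = 58.3,
                                  block_ms = 9.7)
  expect_lt(max(abs(lh2$lambda - sw$lambda_closed_form)), 0.02 * 0.73)

  # identity jump: the saltation is the transversality correction only,
  # which is also the identity here, so the spectrum is purely the flow's
  sw1 <- make_sawtooth_hybrid(m = -0.4, s = 1)
  lh3 <- lyapunov_spectrum_hybrid(sw1, c(0, 1), t_total = 58.3,
                                  block_ms = 9.7)
  expect_lt(max(abs(lh3$lambda - c(0, -0.4))), 0.01)
})

test_that("omitting the saltation matrix fakes chaos on a periodic orbit", {
  p <- neuron_params(0.2, 2, -56, -10, -99) # periodic regime
  with_s <- lyapunov_spectrum(p, cfg = cfg_fast(), n_blocks = 40)
  without_s <- lyapunov_spectrum(p, cfg = cfg_fast(), n_blocks = 40,
                                 use_saltation = FALSE)
  expect_lt(abs(with_s$lambda1), 1e-3)   # true: marginal + contracting
  expect_lt(with_s$lambda2, 0)
  expect_gt(without_s$lambda1, 0.1)      # artifact: spuriously positive
})

test_that("spectrum is insensitive to the block size at fixed total spikes", {
  l1 <- lyapunov_spectrum(p_chaotic(), n_blocks = 150)$lambda1
  l2 <- lyapunov_spectrum(p_chaotic(), n_blocks = 75,
                          spikes_per_block = 40)$lambda1
  expect_lt(abs(l1 - l2) / l1, 0.02)
})

test_that("divergence estimator agrees in sign and magnitude with the spectrum", {
  # chaotic point: both positive, same order of magnitude
  div16 <- divergence_lyapunov(p_chaotic(), cfg = cfg_fast(), n_trials = 60)
  sal16 <- lyapunov_spectrum(p_chaotic(), cfg = cfg_fast(),
                             n_blocks = 100)$lambda1
  expect_gt(div16, 0)
  expect_gt(sal16, 0)
  expect_lt(abs(div16 - sal16) / sal16, 0.5) # approximate near resets

  div13 <- divergence_lyapunov(p_chaotic(-13), cfg = cfg_fast(),
                               n_trials = 40)
  expect_gt(div13, 0)

  # resting point contracts onto a focus: estimate matches the eigenvalue
  # real part of the linearization at the equilibrium within 5%
  p_rest <- neuron_params(0.2, 2, -56, -16, I = -120)
  tr <- simulate_neuron(p_rest, t_end = 3000, keep_samples = FALSE)
  lam_lin <- max(Re(eigen(izh_jacobian(tr$final_state, p_rest))$values))
  div_rest <- divergence_lyapunov(p_rest, cfg = cfg_fast(), horizon = 2,
                                  n_trials = 100)
  expect_lt(abs(div_rest - lam_lin) / abs(lam_lin), 0.05)

  expect_error(divergence_lyapunov(p_chaotic(), perturbation_size = 0),
               "perturbation")
})

test_that("block transition products compose and degenerate correctly", {
  p <- p_chaotic()
  tr <- simulate_neuron(p, t_end = 1500, cfg = cfg_fast(),
                        with_variational = TRUE, keep_samples = FALSE)
  stopifnot(nrow(tr$spikes) > 8)
  whole <- block_transition(tr, c(3, 6))
  first <- block_transition(tr, c(3, 4))
  second <- block_transition(tr, c(5, 6))
  lhs <- whole$mat * exp(whole$logscale)
  rhs <- (second$mat %*% first$mat) * exp(second$logscale + first$logscale)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-8)

  # a resting trajectory has no saltation factors: block = bare segment Phi
  p_rest <- neuron_params(0.2, 2, -56, -16, I = -120)
  tr0 <- simulate_neuron(p_rest, t_end = 50, keep_samples = FALSE,
                         with_variational = TRUE)
  b0 <- block_transition(tr0)
  expect_equal(b0$mat * exp(b0$logscale), tr0$segments[[1]]$Phi,
               tolerance = 1e-10)
})

test_that("regime classification follows the spectrum/CV thresholds", {
  expect_equal(classify_regime(0.05, -0.1, 0.5, 1000), "chaotic")
  expect_equal(classify_regime(-0.2, -0.5, NA, 0), "resting")
  expect_equal(classify_regime(0.0005, -0.3, 0.0, 500), "periodic")
  expect_equal(classify_regime(0.0005, -0.3, 0.3, 500), "multi-periodic")
  expect_equal(classify_regime(0.05, -0.1, NA, 0), "anomalous")
})
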