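test_that("regular spiking is periodic to solver precision", {
  tr <- simulate_neuron(p_rs(), t_end = 1500, cfg = cfg_fast(0),
                        keep_samples = FALSE)
  sp <- tr$spikes$t_spike[tr$spikes$t_spike > 300]
  expect_gt(length(sp), 10)
  expect_lt(isi_cv(isi(sp)), 0.01)
  # every recorded pre-spike state sits on the threshold
  expect_lt(max(abs(tr$spikes$v_pre - 30)), 1e-6)
  # spike times strictly increasing
  expect_true(all(diff(tr$spikes$t_spike) > 0))
})

test_that("deep subthreshold input gives a resting (non-firing) trajectory", {
  p <- neuron_params(0.2, 2, -56, -16, I = -120)
  tr <- simulate_neuron(p, t_end = 2000, keep_samples = FALSE)
  expect_equal(nrow(tr$spikes), 0)
  # converged to an equilibrium: the flow at the final state vanishes
  f <- izh_flow(tr$final_state, p)
  expect_lt(max(abs(f)), 1e-4)
})

test_that("variational segments reproduce the matrix exponential on a linear flow", {
  sys <- make_linear_hybrid(c(-0.3, -1.2))
  r <- simulate_hybrid(sys, c(0.2, 0.4), t_end = 3, with_variational = TRUE)
  expect_equal(nrow(r$events), 0)
  E <- as.matrix(Matrix::expm(sys$M * 3))
  expect_lt(max(abs(r$segments[[1]]$Phi - E)), 1e-6)

  # zero flow matrix: Phi stays the identity
  sys0 <- make_linear_hybrid(c(0, 0))
  r0 <- simulate_hybrid(sys0, c(0.1, 0.1), t_end = 5, with_variational = TRUE)
  expect_lt(max(abs(r0$segments[[1]]$Phi - diag(2))), 1e-8)
})

test_that("spike times converge under tolerance refinement", {
  s1 <- simulate_neuron(p_rs(), t_end = 500, cfg = integrator_config(),
                        keep_samples = FALSE)$spikes$t_spike
  s2 <- simulate_neuron(p_rs(), t_end = 500,
                        cfg = integrator_config(rtol = 5e-11, atol = 5e-13),
                        keep_samples = FALSE)$spikes$t_spike
  expect_equal(length(s1), length(s2))
  expect_lt(max(abs(s1 - s2)), 1e-7)
})

test_that("transition matrices compose multiplicatively over sub-segments", {
  # event-free system (deep subthreshold), split at an interior time
  p <- neuron_params(0.2, 2, -56, -16, I = -120)
  a <- simulate_neuron(p, t_end = 6, cfg = cfg_fast(0),
                       with_variational = TRUE, keep_samples = FALSE)
  b <- simulate_neuron(p, init = a$final_state, t_end = 12,
                       cfg = cfg_fast(0), with_variational = TRUE,
                       keep_samples = FALSE)
  whole <- simulate_neuron(p, t_end = 12, cfg = cfg_fast(0),
                           with_variational = TRUE, keep_samples = FALSE)
  expect_equal(nrow(whole$spikes), 0)
  P2 <- b$segments[[1]]$Phi %*% a$segments[[1]]$Phi
  expect_lt(max(abs(P2 - whole$segments[[1]]$Phi)), 1e-6)
})

test_that("refine_event localizes a bracketed crossing", {
  cfg <- cfg_fast(0)
  tr <- simulate_neuron(p_rs(), t_end = 200, cfg = cfg, keep_samples = TRUE)
  t1 <- tr$spikes$t_spike[1]
  i <- max(which(tr$samples$t < t1 - 0.5))
  left <- izh_state(tr$samples$t[i], tr$samples$v[i], tr$samples$u[i])
  right <- izh_state(t1 + 0.2, 35, tr$spikes$u_pre[1]) # nominal upper end
  ev <- refine_event(list(left, right), p_rs(), cfg = cfg)
  expect_lt(abs(ev$t_spike - t1), 1e-6)
  expect_equal(ev$state_pre$v, 30)
  expect_equal(ev$state_post$v, -65)

  # degenerate bracket: left end already at threshold
  atev <- izh_state(5, 30, -8)
  ev2 <- refine_event(list(atev, atev), p_rs(), cfg = cfg)
  expect_equal(ev2$t_spike, 5)

  # non-straddling bracket violates the contract
  expect_error(refine_event(list(izh_state(0, -60, -10),
                                 izh_state(1, -55, -10)), p_rs(), cfg = cfg),
               "straddle")
})

test_that("trajectory export and spike-time round trip work", {
  tr <- simulate_neuron(p_rs(), t_end = 120, cfg = cfg_fast(0))
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f1)
  back <- read.csv(f1)
  expect_named(back, c("t", "v", "u"))
  expect_equal(nrow(back), nrow(tr$samples))

  f2 <- withr::local_tempfile(fileext = ".txt")
  write_spike_times(tr$spikes$t_spike, f2)
  expect_equal(read_spike_times(f2), tr$spikes$t_spike, tolerance = 1e-12)
})
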