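test_that("section series matches spikes and the known attractor ranges", {
  lr16 <- lyapunov_spectrum(p_chaotic(), cfg = cfg_fast(), n_blocks = 30)
  ss <- section_series(lr16)
  expect_equal(nrow(ss), nrow(lr16$spikes))
  expect_true(all(diff(ss$t) > 0))
  # chaotic attractor fills roughly -102 ... -90 on the section
  expect_lt(min(ss$u), -100)
  expect_gt(max(ss$u), -92)
  expect_true(all(ss$u > -104 & ss$u < -79))

  # d = -11: the series settles on a fixed point near -98.6
  lr11 <- lyapunov_spectrum(p_chaotic(-11), cfg = cfg_fast(3000),
                            n_blocks = 20)
  late <- tail(section_series(lr11)$u, 50)
  expect_lt(diff(range(late)), 0.05)
  expect_lt(abs(mean(late) - -98.6), 0.2)
})

test_that("the shooting map reproduces the observed section dynamics", {
  p <- p_chaotic()
  lr <- lyapunov_spectrum(p, cfg = cfg_fast(), n_blocks = 10)
  u <- section_series(lr)$u
  for (i in 20:119) {
    expect_lt(abs(evaluate_psi(u[i], 1, p)$u - u[i + 1]), 1e-6)
  }
})

test_that("psi iterates compose: psi^2 = psi o psi", {
  p <- p_chaotic()
  for (u0 in c(-101, -98.5, -93)) {
    one <- evaluate_psi(u0, 1, p)$u
    two_direct <- evaluate_psi(u0, 2, p)$u
    two_chained <- evaluate_psi(one, 1, p)$u
    expect_lt(abs(two_direct - two_chained), 1e-6)
  }
  expect_error(evaluate_psi(-200, 1, p), "admissible")
  expect_error(evaluate_psi(-98, 0, p), "l must be")
})

test_that("psi at d = -16 has the stretch-and-fold single-hump shape", {
  p <- p_chaotic()
  # rising wing at the low-u end, falling wing at the high-u end
  lo <- seq(-101.5, -99.8, length.out = 8)
  hi <- seq(-96.5, -90.5, length.out = 12)
  psi_lo <- vapply(lo, function(u) evaluate_psi(u, 1, p)$u, numeric(1))
  psi_hi <- vapply(hi, function(u) evaluate_psi(u, 1, p)$u, numeric(1))
  expect_true(all(diff(psi_lo) > 0))
  expect_true(all(diff(psi_hi) < 0))
})

test_that("psi^2 fixed points at d = -11 match the known three-point structure", {
  p <- p_chaotic(-11)
  fps <- find_fixed_points(2, c(-103, -88), p, n_grid = 150)
  expect_equal(nrow(fps), 3)
  expect_true(all(fps$residual < 1e-8))
  fps <- fps[order(fps$u_star), ]
  expect_equal(fps$u_star, c(-101.5, -98.5, -91.5), tolerance = 0.01)
  expect_lt(abs(fps$mu[2]), 1)       # middle point stable
  expect_gt(fps$mu[1], 1)            # outer pair unstable
  expect_gt(fps$mu[3], 1)

  # a fixed point of psi is a fixed point of psi^2 (iterate nesting)
  fp1 <- find_fixed_points(1, c(-99.5, -97.5), p, n_grid = 60)
  expect_gte(nrow(fp1), 1)
  expect_lt(min(abs(fp1$u_star[1] - fps$u_star)), 1e-6)
})

test_that("mu equals the finite-difference derivative of psi^l", {
  p <- p_chaotic(-11)
  fps <- find_fixed_points(2, c(-103, -88), p, n_grid = 150)
  h <- 1e-5
  for (i in seq_len(nrow(fps))) {
    u0 <- fps$u_star[i]
    mu <- fps$mu[i]
    fd <- (evaluate_psi(u0 + h, 2, p)$u -
             evaluate_psi(u0 - h, 2, p)$u) / (2 * h)
    expect_lt(abs(mu - fd) / abs(fd), 1e-3)
  }
})

test_that("laminar statistics behave on constant, uniform and chaotic series", {
  # constant series is all laminar
  st <- laminar_turbulent_stats(rep(-98.6, 100))
  expect_equal(st$laminar_fraction, 1)

  # i.i.d. uniform over width w: P(|u' - u| < delta) = r(2 - r), r = delta/w
  w <- 10; delta <- 0.5; r <- delta / w
  u <- withr::with_seed(11, runif(4000, 0, w))
  frac <- laminar_turbulent_stats(u, delta_laminar = delta)$laminar_fraction
  expect_lt(abs(frac - r * (2 - r)), 0.02)

  expect_error(laminar_turbulent_stats(c(1, 2), lag = 2), "shorter")
})

test_that("laminar fraction decreases from intermittency to turbulent chaos", {
  frac <- vapply(c(-12, -13, -16), function(d) {
    lr <- lyapunov_spectrum(p_chaotic(d), cfg = cfg_fast(), n_blocks = 40)
    laminar_turbulent_stats(lr$spikes$u_pre)$laminar_fraction
  }, numeric(1))
  expect_true(all(diff(frac) < 0))
  expect_gt(frac[1], 2 * frac[3])
})
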