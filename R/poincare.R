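#' Poincare section series
#'
#' The section is the firing surface itself (`v = 30` mV); the series is the
#' pre-reset recovery value `u_i` at each upward crossing, in spike order.
#' An empty series (no spikes) is valid.
#'
#' @param traj a `hybrid_trajectory` or `lyapunov_result` carrying spikes
#' @return data.frame with columns `t` (ms) and `u`
#' @export
section_series <- function(traj) {
  sp <- traj$spikes
  data.frame(t = sp$t_spike, u = sp$u_pre)
}

#' Evaluate the return map psi^l by shooting
#'
#' The map `u_{i+1} = psi(u_i)` sends the pre-reset `u` at one crossing of
#' the firing surface to the next. Since the section is the firing surface,
#' the only self-consistent start for arbitrary `u0` is the post-reset image
#' `(v, u) = (c, u0 + d)`; the trajectory is integrated to the `l`-th next
#' upward crossing. The variational system is co-propagated and chained with
#' the saltation matrices of the `l - 1` intermediate crossings, so the
#' monodromy needed for the stability index comes for free.
#'
#' @param u0 section coordinate (pre-reset `u`)
#' @param l iterate order (>= 1)
#' @param p,s,cfg model, signal, integrator settings
#' @param u_window admissible section window; `u0` outside it errors
#' @param t_cap time cap per iterate (ms); no crossing within `l * t_cap`
#'   raises a non-returning error
#' @return list `u` (the image), `Phi` (2x2 chained transition matrix from
#'   the post-reset start to the final pre-reset crossing), `f_pre` (flow at
#'   the final crossing), `t_cross` (the l crossing times), `u0`, `l`
#' @export
evaluate_psi <- function(u0, l = 1, p, s = signal_params(A = 0),
                         cfg = integrator_config(),
                         u_window = c(-110, -75), t_cap = 1000) {
  if (l < 1) stop("iterate order l must be >= 1", call. = FALSE)
  if (u0 < u_window[1] || u0 > u_window[2]) {
    stop("u0 outside the admissible section window", call. = FALSE)
  }
  parms <- .izh_parms(p, s)
  y <- c(p$c, u0 + p$d, 1, 0, 0, 1)
  t_cur <- 0
  acc <- list(mat = diag(2), logscale = 0)
  t_cross <- numeric(l)
  for (i in seq_len(l)) {
    seg <- .izh_segment(y, t_cur, t_cur + t_cap, parms, cfg)
    last <- seg$out[nrow(seg$out), ]
    if (is.null(seg$troot) || last[[1]] >= t_cur + t_cap - cfg$event_tol) {
      stop(sprintf("non-returning: no crossing within %g ms from u0=%g (iterate %d)",
                   t_cap, u0, i), call. = FALSE)
    }
    t_new <- last[[1]]
    u_pre <- last[[3]]
    acc <- .acc_mult(acc, matrix(last[4:7], 2, 2))
    t_cross[i] <- t_new
    if (i < l) {
      acc <- .acc_mult(acc, saltation_matrix(list(t_spike = t_new,
                                                  u_pre = u_pre), p, s))
      y <- c(p$c, u_pre + p$d, 1, 0, 0, 1)
      t_cur <- t_new
    } else {
      f_pre <- izh_flow(izh_state(t_new, IZH_THRESHOLD, u_pre), p, s)
      res <- list(u = u_pre, Phi = acc$mat * exp(acc$logscale),
                  f_pre = f_pre, t_cross = t_cross, u0 = u0, l = l)
    }
  }
  res
}

#' Stability index of a period-l orbit of the return map
#'
#' The derivative of the `l`-th iterate of the section map at `u0`:
#' the chained transition matrix along the orbit (segment matrices and
#' intermediate saltation matrices) is projected onto the section at the
#' terminal crossing and contracted with the section coordinate direction.
#' The projection accounts for the perturbed trajectory crossing the surface
#' at a slightly shifted time, giving the matrix row `(-udot/vdot, 1)` with
#' the flow evaluated pre-reset at the terminal crossing. `|mu| < 1` is
#' stable, `mu = -1` period doubling, `mu = 1` tangent bifurcation.
#'
#' @param psi_eval result of [evaluate_psi()] (at or near a fixed point)
#' @return the scalar stability index mu
#' @export
stability_mu <- function(psi_eval) {
  f <- psi_eval$f_pre
  if (abs(f[1]) < 1e-12) {
    stop("projection degenerate: terminal crossing is tangential",
         call. = FALSE)
  }
  Pm <- matrix(c(0, -f[2] / f[1], 0, 1), 2, 2)
  (Pm %*% psi_eval$Phi)[2, 2]
}

#' Locate fixed points of psi^l in a window
#'
#' Evaluates `g(u) = psi^l(u) - u` on a regular grid, brackets sign changes,
#' polishes each root with `uniroot`, and annotates each fixed point with
#' its stability index. Sub-intervals where the map does not return are
#' skipped (the map is undefined there).
#'
#' @param l iterate order
#' @param search_window numeric length-2 window of `u`
#' @param p,s,cfg model, signal, integrator settings
#' @param n_grid grid resolution for bracketing (default 400)
#' @param root_tol residual tolerance for polishing
#' @return data.frame: `u_star`, `l`, `mu`, `residual`; zero rows if none
#' @export
find_fixed_points <- function(l, search_window, p, s = signal_params(A = 0),
                              cfg = integrator_config(), n_grid = 400,
                              root_tol = 1e-9) {
  grid <- seq(search_window[1], search_window[2], length.out = n_grid)
  g <- function(u) evaluate_psi(u, l, p, s, cfg)$u - u
  gv <- vapply(grid, function(u) tryCatch(g(u), error = function(e) NA_real_),
               numeric(1))
  roots <- numeric(0)
  for (i in seq_len(n_grid - 1)) {
    if (is.na(gv[i]) || is.na(gv[i + 1])) next
    if (gv[i] == 0) { roots <- c(roots, grid[i]); next }
    if (gv[i] * gv[i + 1] < 0) {
      r <- uniroot(g, c(grid[i], grid[i + 1]), tol = root_tol)
      roots <- c(roots, r$root)
    }
  }
  if (!length(roots)) {
    return(data.frame(u_star = numeric(0), l = integer(0), mu = numeric(0),
                      residual = numeric(0)))
  }
  res <- lapply(roots, function(u) {
    pe <- evaluate_psi(u, l, p, s, cfg)
    data.frame(u_star = u, l = l, mu = stability_mu(pe),
               residual = abs(pe$u - u))
  })
  res <- do.call(rbind, res)
  # discard brackets that straddle a discontinuity of the map (uniroot
  # converges to a jump, not a root: residual stays large)
  res[res$residual <= 1e-6, , drop = FALSE]
}

#' Locate the tangent bifurcation of a psi^l fixed point in d
#'
#' Follows the stable fixed-point branch of the `l`-th iterate while
#' bisecting on `d`. On the side where the branch exists, the sign of
#' `mu - 1` decides; a `d` where the continued root has vanished (the
#' stable/unstable pair has annihilated) counts as beyond the bifurcation.
#' Converges to `delta_d <= tol_d`.
#'
#' @param l iterate order (the route-to-chaos case is `l = 2`)
#' @param d_range length-2 range of `d` bracketing the bifurcation
#'   (branch must exist at `max(d_range)` and be gone or unstable at
#'   `min(d_range)`)
#' @param p_base [neuron_params()]; its `d` is overridden
#' @param s,cfg signal and integrator settings
#' @param u_guess starting guess for the stable fixed point
#' @param u_halfwidth half-width of the continuation window around the
#'   tracked fixed point
#' @param tol_d bisection tolerance on d
#' @param n_grid grid for root bracketing inside the window
#' @return list `d_star`, `u_star` (last stable fixed point), `mu_last`,
#'   `n_iter`
#' @export
locate_tangent_bifurcation <- function(l = 2, d_range = c(-12.5, -11),
                                       p_base = neuron_params(),
                                       s = signal_params(A = 0),
                                       cfg = integrator_config(),
                                       u_guess = -98.5, u_halfwidth = 1.5,
                                       tol_d = 1e-3, n_grid = 200) {
  stable_fp <- function(d, guess) {
    p <- neuron_params(p_base$a, p_base$b, p_base$c, d, p_base$I)
    fps <- tryCatch(
      find_fixed_points(l, c(guess - u_halfwidth, guess + u_halfwidth),
                        p, s, cfg, n_grid = n_grid),
      error = function(e) NULL)
    if (is.null(fps) || !nrow(fps)) return(NULL)
    st <- fps[fps$mu < 1 & fps$mu > -1, , drop = FALSE]
    if (!nrow(st)) return(NULL)
    st[which.min(abs(st$u_star - guess)), ]
  }
  lo <- min(d_range); hi <- max(d_range)
  fp_hi <- stable_fp(hi, u_guess)
  if (is.null(fp_hi)) {
    stop("no stable fixed point at the upper end of d_range", call. = FALSE)
  }
  if (!is.null(stable_fp(lo, u_guess))) {
    stop("stable fixed point persists at the lower end of d_range; widen it",
         call. = FALSE)
  }
  guess <- fp_hi$u_star
  last_fp <- fp_hi
  n_iter <- 0L
  while (hi - lo > tol_d) {
    mid <- (lo + hi) / 2
    fp <- stable_fp(mid, guess)
    n_iter <- n_iter + 1L
    if (is.null(fp)) {
      lo <- mid
    } else {
      hi <- mid
      guess <- fp$u_star
      last_fp <- fp
    }
  }
  list(d_star = (lo + hi) / 2, u_star = last_fp$u_star,
       mu_last = last_fp$mu, n_iter = n_iter)
}

#' Laminar / turbulent episode statistics of a section series
#'
#' Intermittency diagnostics on the `u_i` series: index `i` is laminar when
#' `|u_{i+lag} - u_i| < delta_laminar` (the `lag = 2` default matches the
#' use of the `(u_i, u_{i+2})` map in the route-to-chaos analysis).
#'
#' @param u_values numeric section series
#' @param delta_laminar laminar threshold in u units (default 0.5)
#' @param lag map iterate used for the increment (default 2)
#' @return list `laminar_fraction`, `mean_episode_length`,
#'   `episode_lengths` (table), `labels` (logical vector)
#' @export
laminar_turbulent_stats <- function(u_values, delta_laminar = 0.5, lag = 2) {
  n <- length(u_values)
  if (n <= lag) stop("series shorter than the lag", call. = FALSE)
  lam <- abs(u_values[(1 + lag):n] - u_values[1:(n - lag)]) < delta_laminar
  r <- rle(lam)
  ep <- r$lengths[r$values]
  list(laminar_fraction = mean(lam),
       mean_episode_length = if (length(ep)) mean(ep) else 0,
       episode_lengths = if (length(ep)) table(ep) else table(integer(0)),
       labels = lam)
}
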