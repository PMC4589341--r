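#' Saltation matrix at a reset event
#'
#' The variational flow is discontinuous at the state-dependent reset; the
#' first-order correction carrying a tangent vector across the jump is the
#' saltation matrix
#' \deqn{S = [[\dot v^+/\dot v^-, 0], [(\dot u^+ - \dot u^-)/\dot v^-, 1]]}
#' with the flow evaluated immediately before (at `v = 30, u^-`) and after
#' (at `v = c, u^- + d`) the reset, both at the event time (the signal term
#' enters both sides). A vanishing transversal component `\dot v^-` means the
#' crossing is tangential and the correction is undefined.
#'
#' @param event a spike event: list or one-row data.frame with `t_spike`,
#'   `u_pre` (and implicitly `v_pre = 30`)
#' @param p [neuron_params()]
#' @param s [signal_params()]
#' @return 2x2 saltation matrix with attributes `f_pre`, `f_post`
#' @export
saltation_matrix <- function(event, p, s = signal_params(A = 0)) {
  t_ev <- event$t_spike
  u_pre <- event$u_pre
  f_pre <- izh_flow(izh_state(t_ev, IZH_THRESHOLD, u_pre), p, s)
  f_post <- izh_flow(izh_state(t_ev, p$c, u_pre + p$d), p, s)
  if (abs(f_pre[1]) < 1e-12) {
    stop("tangential crossing: |vdot_pre| below 1e-12", call. = FALSE)
  }
  S <- saltation_general(f_pre, f_post,
                         Dg = matrix(c(0, 0, 0, 1), 2, 2),
                         n = c(1, 0))
  attr(S, "f_pre") <- f_pre
  attr(S, "f_post") <- f_post
  S
}

#' Generic saltation matrix
#'
#' For a flow `f`, an event surface with normal `n`, and a jump map with
#' Jacobian `Dg`: `S = Dg + (f(x+) - Dg f(x-)) n' / (n . f(x-))`. Reduces to
#' the reset-specific form of [saltation_matrix()] for the Izhikevich jump.
#'
#' @param f_pre,f_post flow vectors just before / after the jump
#' @param Dg 2x2 Jacobian of the jump map
#' @param n event-surface normal (gradient of the event function)
#' @return 2x2 matrix
#' @export
saltation_general <- function(f_pre, f_post, Dg, n) {
  denom <- sum(n * f_pre)
  if (abs(denom) < 1e-12) {
    stop("tangential crossing: event-normal flow component vanishes",
         call. = FALSE)
  }
  S <- Dg + (cbind(unname(f_post) - as.numeric(Dg %*% f_pre)) %*%
               rbind(unname(n))) / denom
  dimnames(S) <- NULL
  S
}

# Multiply accumulated block matrix, keeping a separate log scale so that
# products over many expanding segments do not overflow.
.acc_mult <- function(acc, M) {
  R <- M %*% acc$mat
  nm <- max(abs(R))
  if (nm == 0) stop("singular transition product", call. = FALSE)
  list(mat = R / nm, logscale = acc$logscale + log(nm))
}

#' Ordered transition product over one block
#'
#' Chains per-segment state-transition matrices `Phi` interleaved with the
#' saltation matrices of the events separating them, in time order:
#' `Phi_block = Phi_m S_{m-1} ... S_1 Phi_1`. The result is returned
#' scaled to unit max-norm together with the accumulated log magnitude, to
#' avoid overflow over strongly expanding blocks.
#'
#' @param traj a variational `hybrid_trajectory` from [simulate_neuron()]
#' @param spike_range integer range `c(first, last)` of spikes in the block,
#'   or NULL for the whole trajectory
#' @return list `mat` (2x2, unit max-norm), `logscale`
#' @export
block_transition <- function(traj, spike_range = NULL) {
  if (!length(traj$segments)) {
    stop("trajectory carries no variational segments", call. = FALSE)
  }
  p <- traj$params; s <- traj$signal
  nspk <- nrow(traj$spikes)
  if (is.null(spike_range)) spike_range <- c(1L, nspk)
  i0 <- spike_range[1]; i1 <- spike_range[2]
  # segment j ends at spike j (for j <= nspk); block spans segments i0..i1,
  # each segment's Phi followed by the saltation of its terminal spike
  acc <- list(mat = diag(2), logscale = 0)
  segs <- if (nspk == 0) seq_along(traj$segments) else seq.int(i0, i1)
  for (j in segs) {
    acc <- .acc_mult(acc, traj$segments[[j]]$Phi)
    if (j <= nspk) {
      S <- saltation_matrix(traj$spikes[j, ], p, s)
      acc <- .acc_mult(acc, S)
    }
  }
  acc
}

#' Lyapunov spectrum with saltation matrices
#'
#' Computes the two Lyapunov exponents of the hybrid system. The tangent
#' system is integrated along the trajectory between spikes (state-transition
#' matrices `Phi`), the saltation matrix is inserted at every reset, and the
#' trajectory is cut into blocks bounded by spike count (default 20 spikes)
#' or by a time cap (default 1000 ms) for sparsely firing regimes. Per block
#' the eigenvalue moduli of the chained transition product are taken; the
#' exponents are the summed log moduli divided by the total time spanned:
#' \deqn{\lambda_j = \frac{1}{T^N - T^0} \sum_k \log |l_j^k|.}
#' Eigenvalue branches are paired across blocks by sorted modulus.
#'
#' @param p,s,init,cfg model, signal, initial state and integrator settings;
#'   the transient `cfg$t_transient` is discarded first
#' @param n_blocks number of blocks N (default 200)
#' @param spikes_per_block block size in spikes (default 20)
#' @param block_cap_ms per-block time cap (default 1000 ms)
#' @param use_saltation insert saltation matrices at resets (TRUE). Setting
#'   FALSE reproduces the well-known artifact that the uncorrected maximum
#'   exponent is positive even on periodic orbits; exposed for that
#'   regression only.
#' @param t_min continue adding blocks until at least this much post-transient
#'   time (ms) is covered, even after `n_blocks` is reached (0 = off); used
#'   when the same pass must also provide spikes for response metrics
#' @return a `lyapunov_result`: `lambda1`, `lambda2` (1/ms), `n_blocks`,
#'   `spikes_per_block`, `block_cap_ms`, `per_block_eigs` (N x 2 matrix of
#'   log moduli), `total_time`, and `spikes` (data.frame t_spike, u_pre of
#'   every spike seen inside the blocks)
#' @export
lyapunov_spectrum <- function(p, s = signal_params(A = 0),
                              init = default_init(p),
                              cfg = integrator_config(),
                              n_blocks = 200, spikes_per_block = 20,
                              block_cap_ms = 1000, use_saltation = TRUE,
                              t_min = 0) {
  if (n_blocks < 1) stop("n_blocks must be >= 1", call. = FALSE)
  state0 <- init
  if (cfg$t_transient > 0) {
    warm <- simulate_neuron(p, s, init, t_end = init$t + cfg$t_transient,
                            cfg = cfg, keep_samples = FALSE)
    state0 <- warm$final_state
  }
  parms <- .izh_parms(p, s)
  y <- c(state0$v, state0$u, 1, 0, 0, 1)
  t_cur <- state0$t
  block_t0 <- t_cur
  acc <- list(mat = diag(2), logscale = 0)
  nspk_block <- 0L
  eig_list <- list()
  block_len <- numeric(0)
  k <- 1L
  sp_t <- sp_u <- numeric(0)

  close_block <- function(t_close) {
    ev <- eigen(acc$mat, only.values = TRUE)$values
    lv <- sort(log(Mod(ev)) + acc$logscale, decreasing = TRUE)
    eig_list[[k]] <<- lv
    block_len[k] <<- t_close - block_t0
    k <<- k + 1L
    acc <<- list(mat = diag(2), logscale = 0)
    block_t0 <<- t_close
    nspk_block <<- 0L
  }

  t_start <- t_cur
  while (k <= n_blocks || (block_t0 - t_start) < t_min) {
    t_target <- block_t0 + block_cap_ms
    seg <- .izh_segment(y, t_cur, t_target, parms, cfg)
    last <- seg$out[nrow(seg$out), ]
    t_new <- last[[1]]
    Phi_seg <- matrix(last[4:7], 2, 2)
    acc <- .acc_mult(acc, Phi_seg)
    if (!is.null(seg$troot) && t_new < t_target - cfg$event_tol) {
      u_pre <- last[[3]]
      sp_t <- c(sp_t, t_new); sp_u <- c(sp_u, u_pre)
      if (use_saltation) {
        acc <- .acc_mult(acc, saltation_matrix(list(t_spike = t_new,
                                                    u_pre = u_pre), p, s))
      }
      nspk_block <- nspk_block + 1L
      if (nspk_block >= spikes_per_block) close_block(t_new)
      y <- c(p$c, u_pre + p$d, 1, 0, 0, 1)
      t_cur <- t_new
    } else {
      # time cap reached (possibly without any spike)
      y <- c(as.numeric(last[2:3]), 1, 0, 0, 1)
      t_cur <- t_new
      close_block(t_new)
    }
  }

  eigs <- do.call(rbind, eig_list)
  total_time <- sum(block_len)
  lam <- colSums(eigs) / total_time
  structure(list(lambda1 = lam[1], lambda2 = lam[2],
                 n_blocks = nrow(eigs), spikes_per_block = spikes_per_block,
                 block_cap_ms = block_cap_ms, per_block_eigs = eigs,
                 total_time = total_time,
                 spikes = data.frame(t_spike = sp_t, u_pre = sp_u),
                 final_state = izh_state(t_cur, y[1], y[2]),
                 params = p, signal = s, use_saltation = use_saltation),
            class = "lyapunov_result")
}

#' @export
print.lyapunov_result <- function(x, ...) {
  cat(sprintf("Lyapunov spectrum: lambda1 = %.5f, lambda2 = %.5f [1/ms]  (%d blocks, %.0f ms)\n",
              x$lambda1, x$lambda2, x$n_blocks, x$total_time))
  invisible(x)
}

#' Two-trajectory divergence estimate of the maximum exponent
#'
#' Classic perturbation-growth estimate: a companion trajectory offset by
#' `perturbation_size` is co-integrated over windows of length `horizon`,
#' the log stretch of the separation is averaged, and the companion is
#' renormalized back to the original offset after each window. Near resets
#' the separation is corrupted by the jump (the two trajectories reset at
#' slightly different times), so this estimator is approximate and serves
#' only as a sign/magnitude cross-check of [lyapunov_spectrum()].
#'
#' @param p,s,init,cfg model and integrator settings
#' @param perturbation_size initial separation (must be > 0)
#' @param horizon window length tau (ms)
#' @param n_trials number of renormalization windows
#' @return estimated lambda1 (1/ms)
#' @export
divergence_lyapunov <- function(p, s = signal_params(A = 0),
                                init = default_init(p),
                                cfg = integrator_config(),
                                perturbation_size = 1e-7, horizon = 5,
                                n_trials = 200) {
  if (perturbation_size <= 0) {
    stop("perturbation_size must be > 0", call. = FALSE)
  }
  warm <- simulate_neuron(p, s, init, t_end = init$t + cfg$t_transient,
                          cfg = cfg, keep_samples = FALSE)
  x <- warm$final_state
  dir <- c(1, 1) / sqrt(2)
  xp <- izh_state(x$t, x$v + perturbation_size * dir[1],
                  x$u + perturbation_size * dir[2])
  logsum <- 0
  for (i in seq_len(n_trials)) {
    a <- simulate_neuron(p, s, x, t_end = x$t + horizon, cfg = cfg,
                         keep_samples = FALSE)
    b <- simulate_neuron(p, s, xp, t_end = xp$t + horizon, cfg = cfg,
                         keep_samples = FALSE)
    x <- a$final_state
    dvec <- c(b$final_state$v - x$v, b$final_state$u - x$u)
    dlen <- sqrt(sum(dvec^2))
    if (dlen == 0) dvec <- perturbation_size * dir else {
      logsum <- logsum + log(dlen / perturbation_size)
      dvec <- dvec * (perturbation_size / dlen)
    }
    xp <- izh_state(x$t, x$v + dvec[1], x$u + dvec[2])
  }
  logsum / (n_trials * horizon)
}

#' Classify the dynamical regime of one parameter point
#'
#' Applies the spectrum/CV rules: `lambda1 > eps_chaos` is chaotic; a
#' spiking state with `|lambda1| <= eps_chaos` and `lambda2 < 0` is periodic
#' (multi-periodic when `CV > eps_cv`); a non-spiking state with both
#' exponents negative is resting. A positive `lambda1` without any spikes is
#' inconsistent and flagged.
#'
#' @param lambda1,lambda2 Lyapunov exponents (1/ms)
#' @param cv coefficient of variation of the inter-spike intervals (may be
#'   NA for non-spiking states)
#' @param spike_count number of spikes observed
#' @param eps_chaos threshold on lambda1 (default 1e-3 / ms)
#' @param eps_cv threshold on CV (default 1e-2)
#' @return one of "resting", "periodic", "multi-periodic", "chaotic",
#'   "anomalous"
#' @export
classify_regime <- function(lambda1, lambda2, cv, spike_count,
                            eps_chaos = 1e-3, eps_cv = 1e-2) {
  if (lambda1 > eps_chaos && spike_count == 0) return("anomalous")
  if (lambda1 > eps_chaos) return("chaotic")
  if (spike_count == 0) {
    if (lambda1 < 0 && lambda2 < 0) return("resting")
    return("anomalous")
  }
  if (abs(lambda1) <= eps_chaos && lambda2 < 0) {
    if (!is.na(cv) && cv > eps_cv) return("multi-periodic")
    return("periodic")
  }
  # weakly contracting spiking states: treat as periodic-side
  if (lambda1 <= eps_chaos) {
    if (!is.na(cv) && cv > eps_cv) return("multi-periodic")
    return("periodic")
  }
  "anomalous"
}

#' Lyapunov spectrum of a linear hybrid calibration system
#'
#' Same block algorithm as [lyapunov_spectrum()] but driven by a
#' [make_linear_hybrid()] system, whose spectrum is known in closed form.
#'
#' @param sys a `hybrid_system`
#' @param init numeric initial state
#' @param t_total total integration time (ms)
#' @param cfg [integrator_config()] (`t_transient` is not applied)
#' @param block_ms block length (ms)
#' @return list `lambda` (sorted decreasing), `n_blocks`
#' @export
lyapunov_spectrum_hybrid <- function(sys, init, t_total = 100,
                                     cfg = integrator_config(),
                                     block_ms = 10) {
  n_blocks <- max(1L, floor(t_total / block_ms))
  state <- init
  t_cur <- 0
  logs <- matrix(NA_real_, n_blocks, 2)
  for (k in seq_len(n_blocks)) {
    run <- simulate_hybrid(sys, state, t_end = t_cur + block_ms, cfg = cfg,
                           with_variational = TRUE)
    acc <- list(mat = diag(2), logscale = 0)
    nev <- nrow(run$events)
    for (j in seq_along(run$segments)) {
      acc <- .acc_mult(acc, run$segments[[j]]$Phi)
      if (j <= nev) {
        st_pre <- as.numeric(run$events[j, c("y1_pre", "y2_pre")])
        st_post <- as.numeric(run$events[j, c("y1_post", "y2_post")])
        f_pre <- as.numeric(sys$M %*% st_pre + sys$k)
        f_post <- as.numeric(sys$M %*% st_post + sys$k)
        acc <- .acc_mult(acc, saltation_general(f_pre, f_post, sys$Jg, sys$n))
      }
    }
    ev <- eigen(acc$mat, only.values = TRUE)$values
    logs[k, ] <- sort(log(Mod(ev)) + acc$logscale, decreasing = TRUE)
    state <- run$final_state
    # simulate_hybrid runs on its own clock starting at 0; the linear
    # calibration systems are autonomous, so only elapsed time matters
    t_cur <- 0
  }
  list(lambda = colSums(logs) / (n_blocks * block_ms), n_blocks = n_blocks)
}
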