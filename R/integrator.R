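#' Integrator configuration
#'
#' Settings for the event-detecting hybrid integration. The solver is
#' `deSolve::lsodar`, the root-finding variant of the Livermore multistep
#' solver that switches automatically between Adams and backward
#' differentiation formulae; spike times are localized by its internal root
#' polishing. Defaults are deliberately tight: the chaotic regimes of this
#' model are known to be misjudged under loose integration of the reset.
#'
#' @param rtol,atol relative / absolute solver tolerances
#' @param max_step maximum internal step (ms)
#' @param event_tol time tolerance for spike localization (ms)
#' @param t_transient warm-up time (ms) discarded before statistics
#' @param sample_dt spacing of dense output samples (ms)
#' @param method_label identifier of the scheme (informational)
#' @return an object of class `integrator_config`
#' @export
integrator_config <- function(rtol = 1e-10, atol = 1e-12, max_step = 0.05,
                              event_tol = 1e-9, t_transient = 3000,
                              sample_dt = 0.1,
                              method_label = "lsodar (Livermore, auto Adams/BDF, root-finding)") {
  if (rtol <= 0 || atol <= 0 || event_tol <= 0) {
    stop("tolerances must be positive", call. = FALSE)
  }
  if (t_transient < 0) stop("t_transient must be >= 0", call. = FALSE)
  structure(list(rtol = rtol, atol = atol, max_step = max_step,
                 event_tol = event_tol, t_transient = t_transient,
                 sample_dt = sample_dt, method_label = method_label),
            class = "integrator_config")
}

#' Default initial condition
#'
#' The cold-start state used when no initial condition is given:
#' `(v0, u0) = (c, b c)` at `t = 0` (the post-reset voltage with `u` on the
#' u-nullcline at that voltage).
#'
#' @param p [neuron_params()]
#' @return an [izh_state()]
#' @export
default_init <- function(p) {
  izh_state(t = 0, v = p$c, u = p$b * p$c)
}

.izh_parms <- function(p, s) {
  c(p$a, p$b, p$I, s$A, s$f0, s$phase_origin)
}

#' Low-level one-segment integration (compiled RHS), stopping at v = 30.
#' @noRd
.izh_segment <- function(y, t_from, t_to, parms, cfg, times = NULL) {
  if (is.null(times)) times <- c(t_from, t_to)
  out <- deSolve::lsodar(y = y, times = times, func = "izh_deriv",
                         parms = parms, dllname = "izhcr",
                         initfunc = "izh_init", rootfunc = "izh_root",
                         nroot = 1L,
                         rtol = cfg$rtol, atol = cfg$atol,
                         hmax = cfg$max_step, maxsteps = 1000000L)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0) {
    stop(sprintf("integration failure (istate=%d) at t=%.6f, last state v=%.4g u=%.4g",
                 istate[1], out[nrow(out), 1], out[nrow(out), 2],
                 out[nrow(out), 3]), call. = FALSE)
  }
  troot <- attr(out, "troot")
  list(out = out, troot = if (length(troot)) troot[1] else NULL)
}

#' Simulate the (extended) Izhikevich neuron
#'
#' Integrates the hybrid system: the smooth flow between spikes, the reset
#' `(v, u) -> (c, u + d)` whenever `v` crosses 30 mV upward, and restart.
#' Optionally co-propagates the 2x2 variational (tangent) system between
#' spikes as a 6-dimensional augmented state; each inter-spike segment then
#' carries its state-transition matrix `Phi` (started at the identity).
#'
#' Zero spikes in `[init$t, t_end]` is a valid outcome (resting regime).
#'
#' @param p [neuron_params()]
#' @param s [signal_params()]; default no signal
#' @param init initial [izh_state()]; default [default_init()]
#' @param t_end end time (ms), must exceed `init$t`
#' @param cfg [integrator_config()]
#' @param with_variational propagate the tangent system and store per-segment
#'   transition matrices
#' @param keep_samples store dense state samples every `cfg$sample_dt` ms
#'   (disable for long runs where only spikes are needed)
#' @return a `hybrid_trajectory`: list with `samples` (data.frame t, v, u),
#'   `spikes` (data.frame t_spike, v_pre, u_pre, v_post, u_post),
#'   `segments` (when variational: list of `t0`, `t1`, `Phi`),
#'   `final_state`, and the parameter/config echo
#' @export
simulate_neuron <- function(p, s = signal_params(A = 0), init = default_init(p),
                            t_end, cfg = integrator_config(),
                            with_variational = FALSE, keep_samples = TRUE) {
  stopifnot(inherits(p, "neuron_params"), inherits(s, "signal_params"))
  if (t_end <= init$t) stop("t_end must exceed init$t", call. = FALSE)
  if (init$v >= IZH_THRESHOLD) {
    stop("initial state must start below the firing threshold", call. = FALSE)
  }
  parms <- .izh_parms(p, s)
  neq <- if (with_variational) 6L else 2L
  y <- c(init$v, init$u)
  if (with_variational) y <- c(y, 1, 0, 0, 1)

  t_cur <- init$t
  samples <- list()
  sp_t <- sp_u <- numeric(0)
  segments <- list()
  nseg <- 0L

  while (t_cur < t_end) {
    times <- if (keep_samples) {
      unique(c(seq(t_cur, t_end, by = cfg$sample_dt), t_end))
    } else c(t_cur, t_end)
    if (length(times) < 2) times <- c(t_cur, t_end)
    seg <- .izh_segment(y, t_cur, t_end, parms, cfg, times = times)
    out <- seg$out
    if (keep_samples) samples[[length(samples) + 1L]] <- out[, 1:3, drop = FALSE]
    last <- out[nrow(out), ]
    t_new <- last[[1]]
    if (!is.null(seg$troot) && t_new < t_end - cfg$event_tol) {
      # spike: record, apply reset, restart
      u_pre <- last[[3]]
      sp_t <- c(sp_t, t_new)
      sp_u <- c(sp_u, u_pre)
      if (with_variational) {
        nseg <- nseg + 1L
        segments[[nseg]] <- list(t0 = t_cur, t1 = t_new,
                                 Phi = matrix(last[4:7], 2, 2))
      }
      y <- c(p$c, u_pre + p$d)
      if (with_variational) y <- c(y, 1, 0, 0, 1)
      t_cur <- t_new
    } else {
      if (with_variational) {
        nseg <- nseg + 1L
        segments[[nseg]] <- list(t0 = t_cur, t1 = t_new,
                                 Phi = matrix(last[4:7], 2, 2))
      }
      y <- as.numeric(last[-1])
      t_cur <- t_end
      final <- izh_state(t = t_new, v = last[[2]], u = last[[3]])
    }
  }
  if (!exists("final", inherits = FALSE)) {
    # t_end coincided with a spike; final state is the post-reset image
    final <- izh_state(t = t_cur, v = y[1], u = y[2])
  }

  samples_df <- if (keep_samples && length(samples)) {
    m <- do.call(rbind, samples)
    df <- data.frame(t = m[, 1], v = m[, 2], u = m[, 3])
    df[!duplicated(df$t), , drop = FALSE]
  } else data.frame(t = numeric(0), v = numeric(0), u = numeric(0))

  spikes <- data.frame(t_spike = sp_t, v_pre = rep(IZH_THRESHOLD, length(sp_t)),
                       u_pre = sp_u, v_post = rep(p$c, length(sp_t)),
                       u_post = sp_u + p$d)

  structure(list(samples = samples_df, spikes = spikes, segments = segments,
                 final_state = final, params = p, signal = s, config = cfg,
                 init = init),
            class = "hybrid_trajectory")
}

#' @export
print.hybrid_trajectory <- function(x, ...) {
  cat(sprintf("hybrid trajectory: t in [%.6g, %.6g] ms, %d spikes, %d samples%s\n",
              x$init$t, x$final_state$t, nrow(x$spikes), nrow(x$samples),
              if (length(x$segments)) sprintf(", %d variational segments",
                                              length(x$segments)) else ""))
  invisible(x)
}

#' Refine a spike event inside a bracketing interval
#'
#' Given two states whose voltages straddle the 30 mV threshold, re-integrate
#' from the left state and localize the upward crossing. A left endpoint
#' already at the threshold is the degenerate bracket and is returned as is.
#'
#' @param bracket list of two [izh_state()]: left (v < 30) and right (v > 30)
#' @param p,s,cfg model, signal and integrator settings
#' @return a list `spike event`: `t_spike`, `state_pre`, `state_post`
#' @export
refine_event <- function(bracket, p, s = signal_params(A = 0),
                         cfg = integrator_config()) {
  left <- bracket[[1]]; right <- bracket[[2]]
  if (abs(left$v - IZH_THRESHOLD) <= cfg$event_tol ||
      isTRUE(all.equal(left$v, IZH_THRESHOLD))) {
    pre <- izh_state(left$t, IZH_THRESHOLD, left$u)
    return(list(t_spike = left$t, state_pre = pre,
                state_post = reset_map(pre, p)))
  }
  if (!(left$v < IZH_THRESHOLD && right$v > IZH_THRESHOLD)) {
    stop("bracket does not straddle the threshold v = 30", call. = FALSE)
  }
  seg <- .izh_segment(c(left$v, left$u), left$t, right$t,
                      .izh_parms(p, s), cfg)
  if (is.null(seg$troot)) {
    stop("no upward crossing found inside the bracket", call. = FALSE)
  }
  last <- seg$out[nrow(seg$out), ]
  pre <- izh_state(t = last[[1]], v = IZH_THRESHOLD, u = last[[3]])
  list(t_spike = last[[1]], state_pre = pre, state_post = reset_map(pre, p))
}

# ---- generic hybrid systems (used by the linear closed-form oracles) ------

#' Simulate a generic planar hybrid system
#'
#' Integrates a system defined by a `hybrid_system` object (see
#' [make_linear_hybrid()]): smooth flow, an event hyperplane crossed in the
#' direction of increasing `n . y`, and an affine jump applied at the event.
#' Used for calibration systems whose transition matrices and Lyapunov
#' spectra have closed forms; the neuron itself has the faster dedicated
#' path in [simulate_neuron()].
#'
#' @param sys a `hybrid_system` object
#' @param init numeric state vector (length 2)
#' @param t_end end time (ms), start is t = 0
#' @param cfg [integrator_config()]
#' @param with_variational carry the tangent system
#' @return list with `events` (data.frame t, y1_pre, y2_pre, y1_post,
#'   y2_post), `segments`, `final_state` (numeric), `final_t`
#' @export
simulate_hybrid <- function(sys, init, t_end, cfg = integrator_config(),
                            with_variational = FALSE) {
  stopifnot(inherits(sys, "hybrid_system"))
  deriv <- function(t, y, parms) {
    st <- y[1:2]
    dy <- as.numeric(sys$M %*% st + sys$k)
    if (length(y) == 6L) {
      Phi <- matrix(y[3:6], 2, 2)
      dPhi <- sys$M %*% Phi
      list(c(dy, as.numeric(dPhi)))
    } else list(dy)
  }
  root <- function(t, y, parms) sum(sys$n * y[1:2]) - sys$h
  y <- init
  if (with_variational) y <- c(y, 1, 0, 0, 1)
  t_cur <- 0
  ev <- list(); segments <- list(); nseg <- 0L
  while (t_cur < t_end) {
    out <- deSolve::lsodar(y = y, times = c(t_cur, t_end), func = deriv,
                           parms = NULL, rootfunc = root,
                           rtol = cfg$rtol, atol = cfg$atol,
                           maxsteps = 1000000L)
    troot <- attr(out, "troot")
    last <- out[nrow(out), ]
    t_new <- last[[1]]
    st_pre <- as.numeric(last[2:3])
    if (with_variational) {
      nseg <- nseg + 1L
      segments[[nseg]] <- list(t0 = t_cur, t1 = t_new,
                               Phi = matrix(last[4:7], 2, 2))
    }
    if (length(troot) && t_new < t_end - cfg$event_tol) {
      # only count crossings in the positive direction
      f_pre <- as.numeric(sys$M %*% st_pre + sys$k)
      if (sum(sys$n * f_pre) <= 0) {
        # tangential or downward: continue without a jump
        y <- c(st_pre, if (with_variational) last[4:7])
        t_cur <- t_new + cfg$event_tol
        next
      }
      st_post <- as.numeric(sys$Jg %*% st_pre + sys$q)
      ev[[length(ev) + 1L]] <- c(t_new, st_pre, st_post)
      y <- st_post
      if (with_variational) y <- c(y, 1, 0, 0, 1)
      t_cur <- t_new
    } else {
      t_cur <- t_end
      final <- st_pre
    }
  }
  if (!exists("final", inherits = FALSE)) final <- y[1:2]
  events <- if (length(ev)) {
    m <- do.call(rbind, ev)
    data.frame(t = m[, 1], y1_pre = m[, 2], y2_pre = m[, 3],
               y1_post = m[, 4], y2_post = m[, 5])
  } else data.frame(t = numeric(0), y1_pre = numeric(0), y2_pre = numeric(0),
                    y1_post = numeric(0), y2_post = numeric(0))
  list(events = events, segments = segments, final_state = final,
       final_t = t_cur, sys = sys)
}
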