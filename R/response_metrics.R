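#' Lagged mutual correlation between cycle histogram and signal
#'
#' For each lag `tau` on a grid spanning `[-T0/2, T0/2]`, computes the
#' Pearson-normalized covariance between the sinusoid evaluated analytically
#' at the shifted bin centers, `S(t~ + tau)`, and the histogram counts
#' `F(t~)`; averages weight the phase bins equally. The maximizing lag is
#' reported; ties resolve to the smallest `|tau|`. `C(tau)` is invariant to
#' affine rescaling of either argument.
#'
#' @param F a [cycle_histogram()]
#' @param s [signal_params()] (the same signal the histogram was built
#'   against)
#' @param tau_step lag grid step (ms, default 0.05 = half a phase bin at the
#'   default binning)
#' @return a `correlation_result`: `tau_grid`, `C_values`, `max_C`,
#'   `tau_at_max`
#' @export
mutual_correlation <- function(F, s, tau_step = 0.05) {
  stopifnot(inherits(F, "cycle_histogram"))
  if (tau_step <= 0) stop("tau_step must be > 0", call. = FALSE)
  counts <- as.numeric(F$counts)
  if (sd(counts) == 0) {
    stop("degenerate histogram: zero variance across bins", call. = FALSE)
  }
  T0 <- F$T0
  taus <- seq(-T0 / 2, T0 / 2, by = tau_step)
  centers <- F$bin_centers
  Cv <- vapply(taus, function(tau) {
    sig <- s$A * sin(2 * pi * s$f0 * (centers + tau))
    suppressWarnings(cor(sig, counts))
  }, numeric(1))
  ok <- which(!is.na(Cv))
  best <- ok[order(-Cv[ok], abs(taus[ok]))][1]
  structure(list(tau_grid = taus, C_values = Cv, max_C = Cv[best],
                 tau_at_max = taus[best]),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("max C(tau) = %.4f at tau = %.3f ms\n", x$max_C, x$tau_at_max))
  invisible(x)
}

.discretize <- function(x, lo, hi, m) {
  if (hi <= lo) return(rep(1L, length(x)))
  idx <- floor((x - lo) / (hi - lo) * m) + 1L
  pmin(pmax(idx, 1L), as.integer(m))
}

#' Mutual information between cycle histogram and signal
#'
#' `MI(F;S) = H(F) - H(F|S)` in bits. The signal values at the phase-bin
#' centers are discretized into `m_s` equal-width states over `[-A, A]`; the
#' firing counts into `m_f` equal-width states over `[0, max F]`, where
#' `m_f` is reduced to `max F` when the maximum count is smaller than the
#' requested state count (counts are integers, so finer states would be
#' empty by construction). Probabilities are occupancy frequencies over the
#' phase bins; `0 log 0 = 0`. Note the signal-state occupancy is not uniform
#' (a sinusoid sampled uniformly in phase has an arcsine amplitude density),
#' which is why occupancies, not assumed-uniform weights, are used.
#'
#' @param F a [cycle_histogram()]
#' @param s [signal_params()]
#' @param m_s number of signal states (default 20)
#' @param m_f requested number of count states (default 20)
#' @return an `mi_result`: `MI`, `H_F`, `H_F_given_S` (bits), `m_s`, `m_f`
#' @export
mutual_information <- function(F, s, m_s = 20, m_f = 20) {
  stopifnot(inherits(F, "cycle_histogram"))
  counts <- as.numeric(F$counts)
  maxF <- max(counts)
  if (maxF == 0) {
    return(structure(list(MI = 0, H_F = 0, H_F_given_S = 0,
                          m_s = m_s, m_f = 0L), class = "mi_result"))
  }
  m_f_used <- as.integer(min(m_f, maxF))
  sig <- s$A * sin(2 * pi * s$f0 * F$bin_centers)
  s_state <- .discretize(sig, -s$A, s$A, m_s)
  f_state <- .discretize(counts, 0, maxF, m_f_used)

  n <- length(counts)
  joint <- table(factor(s_state, levels = seq_len(m_s)),
                 factor(f_state, levels = seq_len(m_f_used))) / n
  p_s <- rowSums(joint)
  p_f <- colSums(joint)
  xlx <- function(p) ifelse(p > 0, p * log2(p), 0)
  H_F <- -sum(xlx(p_f))
  # H(F|S) = -sum_i P(s_i) sum_j P(f_j|s_i) log2 P(f_j|s_i)
  H_FgS <- 0
  for (i in which(p_s > 0)) {
    pc <- joint[i, ] / p_s[i]
    H_FgS <- H_FgS - p_s[i] * sum(xlx(pc))
  }
  H_F <- unname(H_F); H_FgS <- unname(H_FgS)
  structure(list(MI = H_F - H_FgS, H_F = H_F, H_F_given_S = H_FgS,
                 m_s = as.integer(m_s), m_f = m_f_used),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("MI = %.4f bits (H(F) = %.4f, H(F|S) = %.4f; m_s = %d, m_f = %d)\n",
              x$MI, x$H_F, x$H_F_given_S, x$m_s, x$m_f))
  invisible(x)
}

#' Sensitivity map of the signal response over (d, A)
#'
#' For every grid point, simulates the driven neuron, computes the maximum
#' lagged correlation and its delay, and (optionally) the maximum Lyapunov
#' exponent. Per A-row, `d_thr` is the largest `d` with `lambda1 >
#' eps_chaos`; the prompt flag marks points satisfying the double criterion
#' `max C > 0.8` and `|tau| < 1.5` ms. Failed runs are recorded in-row, not
#' fatal.
#'
#' @param d_grid,A_grid parameter grids (non-empty)
#' @param p_base,s_base base parameters; `d` and `A` are overridden
#' @param cfg [integrator_config()]
#' @param duration_ms post-transient simulation length per point
#' @param n_blocks Lyapunov blocks per point (0 to skip lambda1/d_thr)
#' @param eps_chaos chaos threshold on lambda1
#' @return data.frame: d, A, max_C, tau_at_max, lambda1, d_thr (logical:
#'   this point is its row's threshold), prompt (logical), ok (logical)
#' @export
sensitivity_map <- function(d_grid, A_grid, p_base = neuron_params(),
                            s_base = signal_params(A = 0.3, f0 = 0.1),
                            cfg = integrator_config(),
                            duration_ms = 20000, n_blocks = 100,
                            eps_chaos = 1e-3) {
  if (!length(d_grid) || !length(A_grid)) {
    stop("grids must be non-empty", call. = FALSE)
  }
  rows <- list()
  for (A in A_grid) {
    for (d in d_grid) {
      p <- neuron_params(p_base$a, p_base$b, p_base$c, d, p_base$I)
      s <- signal_params(A = A, f0 = s_base$f0)
      row <- tryCatch({
        pt <- characterize_point(p, s, cfg, duration_ms = duration_ms,
                                 n_blocks = n_blocks)
        data.frame(d = d, A = A, max_C = pt$max_C, tau_at_max = pt$tau_at_max,
                   lambda1 = pt$lambda1, ok = TRUE)
      }, error = function(e) {
        data.frame(d = d, A = A, max_C = NA_real_, tau_at_max = NA_real_,
                   lambda1 = NA_real_, ok = FALSE)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out$prompt <- !is.na(out$max_C) & out$max_C > 0.8 &
    abs(out$tau_at_max) < 1.5
  out$d_thr <- FALSE
  for (A in A_grid) {
    sel <- out$A == A & !is.na(out$lambda1) & out$lambda1 > eps_chaos
    if (any(sel)) {
      dmax <- max(out$d[sel])
      out$d_thr[out$A == A & out$d == dmax] <- TRUE
    }
  }
  out
}
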