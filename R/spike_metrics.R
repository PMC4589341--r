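#' Inter-spike intervals
#'
#' @param spike_times ordered spike times (ms)
#' @return numeric vector of intervals `T_k = t_{k+1} - t_k`
#' @export
isi <- function(spike_times) {
  iv <- diff(spike_times)
  if (any(iv <= 0)) stop("spike times must be strictly increasing",
                         call. = FALSE)
  iv
}

#' Coefficient of variation of inter-spike intervals
#'
#' `CV = sd(T_k) / mean(T_k)` with the population (1/n) variance. Zero for
#' perfectly periodic trains, positive for multi-periodic and chaotic
#' firing. Fewer than two intervals leaves the CV undefined (`NA`, with a
#' warning), which is distinct from 0.
#'
#' @param intervals inter-spike intervals (ms), see [isi()]
#' @return the CV (dimensionless), or `NA_real_` if undefined
#' @export
isi_cv <- function(intervals) {
  n <- length(intervals)
  if (n < 2) {
    warning("CV undefined for fewer than two intervals")
    return(NA_real_)
  }
  m <- mean(intervals)
  sqrt(sum((intervals - m)^2) / n) / m
}

#' Mean inter-spike interval
#'
#' @param intervals inter-spike intervals (ms)
#' @return arithmetic mean (ms), `NA` if empty (with a warning)
#' @export
mean_isi <- function(intervals) {
  if (!length(intervals)) {
    warning("mean ISI undefined for an empty interval list")
    return(NA_real_)
  }
  mean(intervals)
}

#' Map spike times to signal phase
#'
#' Folds times by the signal period into `t~ in [-T0/2, T0/2)`:
#' `t~ = ((t + T0/2) mod T0) - T0/2`, so e.g. `6 mod 10 -> t~ = -4`.
#'
#' @param spike_times spike times (ms)
#' @param s [signal_params()]
#' @return phases (ms)
#' @export
spike_phase <- function(spike_times, s) {
  T0 <- s$T0
  ((spike_times - s$phase_origin + T0 / 2) %% T0) - T0 / 2
}

#' Cycle histogram of spike timing against a periodic signal
#'
#' Counts spikes per phase bin over one signal period. Bins are half-open
#' `[edge, next)` with the final bin closed; the phase mapping never
#' produces `t~ = T0/2`, so the closure is a formality. The histogram
#' conserves the spike count exactly.
#'
#' @param spike_times spike times (ms)
#' @param s [signal_params()]
#' @param n_bins number of phase bins (default 100, i.e. 0.1 ms at T0 = 10)
#' @return a `cycle_histogram`: list with `T0`, `bin_edges`, `bin_centers`,
#'   `counts` (integer), `n_spikes_total`
#' @export
cycle_histogram <- function(spike_times, s, n_bins = 100) {
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  T0 <- s$T0
  edges <- seq(-T0 / 2, T0 / 2, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  phases <- spike_phase(spike_times, s)
  idx <- findInterval(phases, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(T0 = T0, bin_edges = edges, bin_centers = centers,
                 counts = as.integer(counts),
                 n_spikes_total = length(spike_times)),
            class = "cycle_histogram")
}

#' @export
print.cycle_histogram <- function(x, ...) {
  cat(sprintf("cycle histogram: %d spikes in %d bins over [%.3g, %.3g) ms\n",
              x$n_spikes_total, length(x$counts), -x$T0 / 2, x$T0 / 2))
  invisible(x)
}

#' Look up the count of the bin containing a phase
#'
#' Convenience accessor, e.g. `histogram_count(h, 2)` for F(2).
#'
#' @param h a [cycle_histogram()]
#' @param phase phase value (ms) in `[-T0/2, T0/2)`
#' @return integer count
#' @export
histogram_count <- function(h, phase) {
  idx <- findInterval(phase, h$bin_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  h$counts[idx]
}
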