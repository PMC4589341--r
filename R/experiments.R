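#' Full characterization of one parameter point
#'
#' The per-point pipeline behind every sweep: simulate after the transient,
#' compute the Lyapunov spectrum (when `n_blocks > 0`), the inter-spike
#' statistics, and — when a signal is present — the cycle histogram with
#' its maximum lagged correlation and mutual information. A single
#' variational pass supplies both the spectrum and the spike train: blocks
#' are extended until at least `duration_ms` of post-transient time is
#' covered.
#'
#' @param p,s,cfg model, signal and integrator settings
#' @param duration_ms post-transient observation time for spike statistics
#' @param n_blocks Lyapunov blocks (0 disables the spectrum; the run is then
#'   a plain fast simulation)
#' @param init initial state; default cold start [default_init()]
#' @param n_bins cycle-histogram bins
#' @param u_sample_max at most this many section points kept for
#'   bifurcation diagrams
#' @return a one-row data.frame (`regime_summary`): parameter echo,
#'   `lambda1`, `lambda2`, `cv`, `mean_isi`, `n_spikes`, `max_C`,
#'   `tau_at_max`, `MI`, `regime`; attribute `u_sample` carries the thinned
#'   section series, attribute `final_state` the end state (for
#'   continuation)
#' @export
characterize_point <- function(p, s = signal_params(A = 0),
                               cfg = integrator_config(),
                               duration_ms = 20000, n_blocks = 100,
                               init = default_init(p), n_bins = 100,
                               u_sample_max = 200) {
  if (n_blocks > 0) {
    lr <- lyapunov_spectrum(p, s, init, cfg, n_blocks = n_blocks)
    spikes <- lr$spikes
    lambda1 <- lr$lambda1; lambda2 <- lr$lambda2
    final_state <- lr$final_state
    # extend spike collection cheaply (no tangent system) if the block run
    # did not yet cover the requested observation window
    span <- final_state$t - (init$t + cfg$t_transient)
    if (span < duration_ms) {
      cfg2 <- cfg; cfg2$t_transient <- 0
      tr <- simulate_neuron(p, s, final_state,
                            t_end = final_state$t + (duration_ms - span),
                            cfg = cfg2, keep_samples = FALSE)
      spikes <- rbind(spikes, tr$spikes[, c("t_spike", "u_pre")])
      final_state <- tr$final_state
    }
  } else {
    tr <- simulate_neuron(p, s, init,
                          t_end = init$t + cfg$t_transient + duration_ms,
                          cfg = cfg, keep_samples = FALSE)
    spikes <- tr$spikes[tr$spikes$t_spike >= init$t + cfg$t_transient, ,
                        drop = FALSE]
    names(spikes)[names(spikes) == "t_spike"] <- "t_spike"
    lambda1 <- NA_real_; lambda2 <- NA_real_
    final_state <- tr$final_state
  }
  nspk <- nrow(spikes)
  iv <- if (nspk >= 2) isi(spikes$t_spike) else numeric(0)
  cv <- if (length(iv) >= 2) isi_cv(iv) else NA_real_
  misi <- if (length(iv)) mean(iv) else NA_real_

  max_C <- tau_at_max <- MI <- NA_real_
  if (s$A > 0 && nspk > 0) {
    h <- cycle_histogram(spikes$t_spike, s, n_bins = n_bins)
    if (sd(as.numeric(h$counts)) > 0) {
      cr <- mutual_correlation(h, s)
      max_C <- cr$max_C; tau_at_max <- cr$tau_at_max
    }
    MI <- mutual_information(h, s)$MI
  }
  regime <- if (n_blocks > 0) {
    classify_regime(lambda1, lambda2, cv, nspk)
  } else NA_character_

  out <- data.frame(a = p$a, b = p$b, c = p$c, d = p$d, I = p$I,
                    A = s$A, f0 = s$f0,
                    lambda1 = lambda1, lambda2 = lambda2, cv = cv,
                    mean_isi = misi, n_spikes = nspk,
                    max_C = max_C, tau_at_max = tau_at_max, MI = MI,
                    regime = regime, stringsAsFactors = FALSE)
  u_sample <- if ("u_pre" %in% names(spikes) && nspk > 0) {
    up <- spikes$u_pre
    if (length(up) > u_sample_max) {
      up[round(seq(1, length(up), length.out = u_sample_max))]
    } else up
  } else numeric(0)
  attr(out, "u_sample") <- u_sample
  attr(out, "final_state") <- final_state
  out
}

.override_param <- function(p, s, name, value) {
  if (name %in% c("a", "b", "c", "d", "I")) {
    pl <- unclass(p); pl[[name]] <- value
    p <- neuron_params(pl$a, pl$b, pl$c, pl$d, pl$I)
  } else if (name %in% c("A", "f0")) {
    sl <- unclass(s); sl[[name]] <- value
    s <- signal_params(sl$A, sl$f0, sl$phase_origin)
  } else {
    stop(sprintf("unknown sweep parameter '%s'", name), call. = FALSE)
  }
  list(p = p, s = s)
}

#' Run a one-parameter sweep
#'
#' Deterministic per-point pipeline (`simulate -> metrics`) over a grid of
#' one model or signal parameter; rows come back in grid order. With
#' `continuation = TRUE` each point starts from the previous point's final
#' state (the conventional way to produce bifurcation diagrams, and a strong
#' transient suppressor); with `FALSE` every point is a cold start. With a
#' `csv_path`, completed points found in the file are skipped and results
#' are appended, making long sweeps resumable. Per-point failures are
#' recorded in-row (`ok = FALSE`) and the sweep continues.
#'
#' @param param parameter name: one of "a", "b", "c", "d", "I", "A", "f0"
#' @param grid numeric grid (non-empty)
#' @param p_base,s_base,cfg base settings
#' @param duration_ms,n_blocks,n_bins forwarded to [characterize_point()]
#' @param continuation carry the previous point's final state
#' @param csv_path optional path for resumable output
#' @return data.frame of per-point rows (see [characterize_point()]) plus
#'   `param`, `value`, `ok`; attribute `u_samples` is a named list of
#'   thinned section series for bifurcation diagrams
#' @export
run_sweep <- function(param, grid, p_base = neuron_params(),
                      s_base = signal_params(A = 0), cfg = integrator_config(),
                      duration_ms = 20000, n_blocks = 100, n_bins = 100,
                      continuation = FALSE, csv_path = NULL) {
  if (!length(grid)) stop("empty sweep grid", call. = FALSE)
  done <- NULL
  if (!is.null(csv_path) && file.exists(csv_path)) {
    done <- read.csv(csv_path)
  }
  rows <- list()
  u_samples <- list()
  init <- NULL
  for (val in grid) {
    if (!is.null(done) && any(abs(done$value - val) < 1e-12)) {
      rows[[length(rows) + 1L]] <- done[which.min(abs(done$value - val)), ,
                                        drop = FALSE]
      next
    }
    ov <- .override_param(p_base, s_base, param, val)
    start <- if (!is.null(init)) init else default_init(ov$p)
    row <- tryCatch({
      pt <- characterize_point(ov$p, ov$s, cfg, duration_ms = duration_ms,
                               n_blocks = n_blocks, init = start,
                               n_bins = n_bins)
      u_samples[[as.character(val)]] <- attr(pt, "u_sample")
      if (continuation) init <- attr(pt, "final_state")
      cbind(data.frame(param = param, value = val, ok = TRUE), pt)
    }, error = function(e) {
      data.frame(param = param, value = val, ok = FALSE,
                 a = NA, b = NA, c = NA, d = NA, I = NA, A = NA, f0 = NA,
                 lambda1 = NA, lambda2 = NA, cv = NA, mean_isi = NA,
                 n_spikes = NA, max_C = NA, tau_at_max = NA, MI = NA,
                 regime = NA_character_)
    })
    rows[[length(rows) + 1L]] <- row
    if (!is.null(csv_path)) {
      out_so_far <- do.call(rbind, rows)
      write.csv(out_so_far, csv_path, row.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "u_samples") <- u_samples
  out
}

#' Spike-timing locking analysis over signal strength
#'
#' At a periodic-regime base point, sweeps the signal amplitude and records
#' the mean inter-spike interval and the distribution of spike phases
#' `t~`. Three zones appear as `A` grows: free-running (mean ISI at the
#' autonomous period, phases spread over the whole period), converging
#' (mean ISI drifting toward `T0`), and locked (mean ISI = T0, phases
#' concentrated at a preferred point).
#'
#' @param A_grid amplitudes to test
#' @param p_base neuron parameters (periodic regime, e.g. `d = -10`)
#' @param s_base signal settings (frequency taken from here)
#' @param cfg integrator settings
#' @param duration_ms post-transient observation window
#' @param phase_sample_max phases kept per point
#' @return data.frame `A`, `mean_isi`, `n_spikes`, `phase_spread` (fraction
#'   of the period covered by the middle 90% of phases);
#'   attribute `phases`: named list of phase samples
#' @export
locking_analysis <- function(A_grid, p_base = neuron_params(d = -10),
                             s_base = signal_params(A = 0, f0 = 0.1),
                             cfg = integrator_config(), duration_ms = 5000,
                             phase_sample_max = 500) {
  rows <- list(); phases <- list()
  for (A in A_grid) {
    s <- signal_params(A = A, f0 = s_base$f0)
    tr <- simulate_neuron(p_base, s, t_end = cfg$t_transient + duration_ms,
                          cfg = cfg, keep_samples = FALSE)
    sp <- tr$spikes$t_spike[tr$spikes$t_spike >= cfg$t_transient]
    iv <- if (length(sp) >= 2) isi(sp) else numeric(0)
    ph <- spike_phase(sp, s)
    if (length(ph) > phase_sample_max) {
      ph <- ph[round(seq(1, length(ph), length.out = phase_sample_max))]
    }
    qs <- if (length(ph)) unname(diff(quantile(ph, c(0.05, 0.95)))) else NA
    rows[[length(rows) + 1L]] <- data.frame(
      A = A, mean_isi = mean_isi(iv), n_spikes = length(sp),
      phase_spread = qs / s$T0)
    phases[[as.character(A)]] <- ph
  }
  out <- do.call(rbind, rows)
  attr(out, "phases") <- phases
  out
}

#' Maximum correlation versus maximum Lyapunov exponent
#'
#' Sweeps `d`, collects per-point `(lambda1, max C)` pairs, and averages
#' `max C` within `lambda1` bins of width `bin_width` — the standard way to
#' expose the unimodal dependence of signal response on the degree of
#' orbital instability near the edge of chaos.
#'
#' @param d_grid grid of `d` (conventionally spanning `[-13.5, -11]`)
#' @param A signal amplitude (default 0.01)
#' @param p_base,s_base,cfg base settings
#' @param bin_width lambda1 bin width (default 0.001 / ms)
#' @param duration_ms,n_blocks per-point effort
#' @return list `points` (data.frame d, lambda1, max_C),
#'   `binned` (data.frame lambda1_bin_center, mean_max_C, n)
#' @export
lambda_vs_response <- function(d_grid, A = 0.01,
                               p_base = neuron_params(),
                               s_base = signal_params(A = 0.01, f0 = 0.1),
                               cfg = integrator_config(), bin_width = 0.001,
                               duration_ms = 20000, n_blocks = 100) {
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  sw <- run_sweep("d", d_grid, p_base,
                  signal_params(A = A, f0 = s_base$f0), cfg,
                  duration_ms = duration_ms, n_blocks = n_blocks)
  pts <- sw[sw$ok & !is.na(sw$max_C),
            c("value", "lambda1", "max_C")]
  names(pts)[1] <- "d"
  bin <- floor(pts$lambda1 / bin_width)
  agg <- aggregate(pts$max_C, by = list(bin = bin),
                   FUN = function(x) c(mean(x), length(x)))
  binned <- data.frame(lambda1_bin_center = (agg$bin + 0.5) * bin_width,
                       mean_max_C = agg$x[, 1], n = agg$x[, 2])
  binned <- binned[order(binned$lambda1_bin_center), ]
  list(points = pts, binned = binned)
}

#' Signal-frequency sweep of the chaotic-resonance response
#'
#' Per frequency: maximum lagged correlation, mutual information, and the
#' Lyapunov spectrum. The histogram support adapts to the period
#' automatically (`T0 = 1/f0`).
#'
#' @param f0_grid frequencies (kHz), within (0, 1]
#' @param p_base neuron parameters (edge-of-chaos default `d = -12.19`)
#' @param A amplitude (default 0.01)
#' @param cfg integrator settings
#' @param duration_ms,n_blocks per-point effort
#' @return data.frame `f0`, `max_C`, `MI`, `lambda1`, `lambda2`
#' @export
frequency_sweep <- function(f0_grid, p_base = neuron_params(d = -12.19),
                            A = 0.01, cfg = integrator_config(),
                            duration_ms = 20000, n_blocks = 100) {
  if (any(f0_grid <= 0 | f0_grid > 1)) {
    stop("f0 grid must lie in (0, 1] kHz", call. = FALSE)
  }
  sw <- run_sweep("f0", f0_grid, p_base, signal_params(A = A, f0 = 0.1),
                  cfg, duration_ms = duration_ms, n_blocks = n_blocks)
  data.frame(f0 = sw$value, max_C = sw$max_C, MI = sw$MI,
             lambda1 = sw$lambda1, lambda2 = sw$lambda2)
}
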