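#' Write / read spike-time lists
#'
#' One spike time (ms) per line, plain text.
#'
#' @param spike_times numeric vector (ms)
#' @param path file path
#' @export
write_spike_times <- function(spike_times, path) {
  writeLines(format(spike_times, digits = 15, trim = TRUE, scientific = FALSE),
             path)
  invisible(path)
}

#' @rdname write_spike_times
#' @export
read_spike_times <- function(path) {
  as.numeric(readLines(path))
}

#' Export a trajectory's dense samples as CSV (columns t, v, u)
#'
#' @param traj a `hybrid_trajectory`
#' @param path file path
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(traj$samples, path, row.names = FALSE)
  invisible(path)
}

#' Export a cycle histogram as CSV (bin center, count)
#'
#' @param h a [cycle_histogram()]
#' @param path file path
#' @export
write_cycle_histogram_csv <- function(h, path) {
  write.csv(data.frame(t_bin_center = h$bin_centers, count = h$counts),
            path, row.names = FALSE)
  invisible(path)
}

#' Export run metadata (parameters and integrator settings) as JSON
#'
#' @param p,s,cfg parameter bundles
#' @param path file path
#' @param extra optional named list merged into the record
#' @export
write_run_metadata <- function(p, s, cfg, path, extra = list()) {
  rec <- c(list(neuron = unclass(p), signal = unclass(s)[c("A", "f0", "phase_origin")],
                integrator = unclass(cfg),
                note = "fully deterministic: no RNG in the dynamical core"),
           extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
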