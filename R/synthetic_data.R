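#' Phase-locked synthetic spike train
#'
#' One spike per signal period at phase `t~0`, with wrapped-Gaussian jitter
#' (phase is circular, so the jitter is wrapped into one period). The
#' degenerate `jitter_sd = 0` train is perfectly periodic (CV = 0) and its
#' cycle histogram occupies a single bin. Reproducible from the seed; the
#' seed is a mandatory argument and the caller's RNG state is untouched.
#'
#' @param T0 signal period (ms)
#' @param phase locking phase `t~0` in `[-T0/2, T0/2]`
#' @param jitter_sd jitter standard deviation (ms, >= 0)
#' @param n_spikes number of spikes (periods)
#' @param seed RNG seed (required)
#' @return a `synthetic_train`: list with `times`, `generator`, `params`,
#'   `seed`
#' @export
gen_locked_train <- function(T0, phase = 0, jitter_sd = 0, n_spikes, seed) {
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  if (abs(phase) > T0 / 2) stop("|phase| must be <= T0/2", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  times <- if (n_spikes > 0) {
    jit <- if (jitter_sd > 0) {
      withr::with_seed(seed, rnorm(n_spikes, sd = jitter_sd))
    } else numeric(n_spikes)
    # wrap the jittered phase into [-T0/2, T0/2); spike k sits at k T0 + ph
    ph <- ((phase + jit + T0 / 2) %% T0) - T0 / 2
    sort(seq_len(n_spikes) * T0 + ph)
  } else numeric(0)
  structure(list(times = times, generator = "locked",
                 params = list(T0 = T0, phase = phase,
                               jitter_sd = jitter_sd, n_spikes = n_spikes),
                 seed = seed),
            class = "synthetic_train")
}

#' Poisson (uniform-phase) synthetic spike train
#'
#' Homogeneous Poisson process over `[0, duration]`: spike count Poisson
#' with mean `rate * duration`, times uniform. The phase distribution
#' against any period is uniform, making this the independence baseline for
#' the response metrics (correlation near 0, mutual information near 0).
#'
#' @param T0 nominal signal period (ms), recorded for downstream use
#' @param rate spike rate (1/ms, > 0)
#' @param duration train length (ms)
#' @param seed RNG seed (required)
#' @return a `synthetic_train`
#' @export
gen_uniform_train <- function(T0, rate, duration, seed) {
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  times <- if (duration > 0) {
    withr::with_seed(seed, {
      n <- rpois(1, rate * duration)
      # unique(): the RNG grid is ~2^-32, so exact ties occur at large n
      unique(sort(runif(n, 0, duration)))
    })
  } else numeric(0)
  structure(list(times = times, generator = "uniform",
                 params = list(T0 = T0, rate = rate, duration = duration),
                 seed = seed),
            class = "synthetic_train")
}

#' @export
print.synthetic_train <- function(x, ...) {
  cat(sprintf("synthetic %s train: %d spikes (seed %d)\n",
              x$generator, length(x$times), x$seed))
  invisible(x)
}

#' Linear hybrid calibration system
#'
#' A planar affine flow `y' = M y + k` with an event hyperplane
#' `n . y = h` (crossed upward) and an affine jump `y -> Jg y + q`. For a
#' constant-matrix flow the transition matrix is the matrix exponential and
#' the saltation matrix has closed form, so these systems provide
#' independent oracles for the variational integration, the block products,
#' and the Lyapunov spectrum.
#'
#' The default construction takes flow eigenvalues `(e1, e2)` (diagonal M,
#' real) and a scalar `jump_scale` applied to the second coordinate at the
#' event; `jump_scale = 1` is the identity jump. With no events, the
#' Lyapunov spectrum equals the eigenvalue real parts exactly.
#'
#' @param eigenvalues length-2 real flow eigenvalues (diagonal of M)
#' @param jump_scale scalar applied to y2 at events (default 1)
#' @param k affine flow offset (default c(0, 0))
#' @param n,h event normal and level (default: surface y1 = h, h = 1)
#' @param q jump offset (default: reset y1 to 0)
#' @return a `hybrid_system`: `M`, `k`, `n`, `h`, `Jg`, `q`,
#'   `lambda_closed_form` (when available)
#' @export
make_linear_hybrid <- function(eigenvalues, jump_scale = 1, k = c(0, 0),
                               n = c(1, 0), h = 1, q = NULL) {
  M <- diag(eigenvalues)
  Jg <- diag(c(0, jump_scale))
  if (is.null(q)) q <- c(0, 0)
  structure(list(M = M, k = k, n = n, h = h, Jg = Jg, q = q,
                 lambda_closed_form = sort(eigenvalues, decreasing = TRUE)),
            class = "hybrid_system")
}

#' A sawtooth linear hybrid system with closed-form monodromy
#'
#' Flow `y1' = 1, y2' = m y2`; event at `y1 = 1`; jump `y1 -> 0`,
#' `y2 -> s y2`. The crossing period is exactly 1 ms, the saltation matrix
#' is `diag(1, s)` about the flow factor `diag(1, e^m)`, so the per-period
#' monodromy is `diag(1, s e^m)` and the spectrum is `(0, m + log s)` in
#' closed form.
#'
#' @param m flow rate of the second coordinate
#' @param s jump scale of the second coordinate (> 0)
#' @return a `hybrid_system` with `lambda_closed_form = sort(c(0, m + log(s)))`
#' @export
make_sawtooth_hybrid <- function(m = -0.5, s = 1) {
  sys <- structure(list(M = diag(c(0, m)), k = c(1, 0), n = c(1, 0), h = 1,
                        Jg = diag(c(0, s)), q = c(0, 0),
                        lambda_closed_form = sort(c(0, m + log(s)),
                                                  decreasing = TRUE)),
                   class = "hybrid_system")
  sys
}

#' @export
print.hybrid_system <- function(x, ...) {
  cat("linear hybrid system: y' = M y + k, event n.y = h, jump y -> Jg y + q\n")
  invisible(x)
}
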