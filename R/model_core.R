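#' Izhikevich neuron parameters
#'
#' Bundles the five parameters of the Izhikevich model. `a` and `b` set the
#' time scale and sensitivity of the recovery variable `u`, `c` (mV) is the
#' post-spike reset voltage, `d` the post-spike recovery increment, and `I`
#' the DC input current (model units). The canonical chaotic set used
#' throughout the bifurcation analyses is `(a, b, c, I) = (0.2, 2, -56, -99)`
#' with `d` swept; the regular-spiking set is `(0.02, 0.2, -65, 8, 10)`.
#'
#' @param a recovery time scale (1/ms semantics, dimensionless value)
#' @param b recovery sensitivity (dimensionless)
#' @param c post-spike reset voltage (mV)
#' @param d post-spike recovery increment (model units)
#' @param I DC input current (model units)
#' @return an object of class `neuron_params`
#' @examples
#' neuron_params()                 # canonical chaotic set, d = -16
#' neuron_params(d = -10)          # periodic regime
#' @export
neuron_params <- function(a = 0.2, b = 2, c = -56, d = -16, I = -99) {
  vals <- c(a = a, b = b, c = c, d = d, I = I)
  if (!all(is.finite(vals))) {
    stop("neuron parameters must be finite", call. = FALSE)
  }
  structure(as.list(vals), class = "neuron_params")
}

#' Periodic input signal parameters
#'
#' The extended model adds `S(t) = A sin(2 pi f0 t)` to the voltage equation.
#' `f0` is in kHz (cycles per ms), so `f0 = 0.1` gives the period
#' `T0 = 1/f0 = 10` ms. With `A = 0` the extended model reduces exactly to
#' the autonomous one.
#'
#' @param A signal amplitude (same units as the DC current `I`); `A >= 0`
#' @param f0 signal frequency in kHz; must be positive
#' @param phase_origin time offset (ms) defining t = 0 of the sinusoid
#' @return an object of class `signal_params` (with `T0 = 1/f0` attached)
#' @export
signal_params <- function(A = 0, f0 = 0.1, phase_origin = 0) {
  if (!all(is.finite(c(A, f0, phase_origin)))) {
    stop("signal parameters must be finite", call. = FALSE)
  }
  if (A < 0) stop("signal amplitude A must be >= 0", call. = FALSE)
  if (f0 <= 0) stop("signal frequency f0 must be > 0", call. = FALSE)
  structure(list(A = A, f0 = f0, phase_origin = phase_origin, T0 = 1 / f0),
            class = "signal_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("Izhikevich parameters: a=%g b=%g c=%g d=%g I=%g\n",
              x$a, x$b, x$c, x$d, x$I))
  invisible(x)
}

#' @export
print.signal_params <- function(x, ...) {
  cat(sprintf("Signal: A=%g, f0=%g kHz (T0=%g ms)\n", x$A, x$f0, x$T0))
  invisible(x)
}

#' Evaluate the periodic signal S(t)
#'
#' @param t time (ms), vectorized
#' @param s [signal_params()]
#' @return `A sin(2 pi f0 (t - phase_origin))`
#' @export
signal_value <- function(t, s) {
  s$A * sin(2 * pi * s$f0 * (t - s$phase_origin))
}

#' A point of the hybrid state space
#'
#' @param t time (ms)
#' @param v membrane potential (mV)
#' @param u recovery variable (model units)
#' @return a named list of class `izh_state`
#' @export
izh_state <- function(t, v, u) {
  if (!all(is.finite(c(t, v, u)))) {
    stop("state must be finite", call. = FALSE)
  }
  structure(list(t = t, v = v, u = u), class = "izh_state")
}

#' Spike threshold of the model (mV)
#' @keywords internal
IZH_THRESHOLD <- 30

#' Flow field of the (extended) Izhikevich model
#'
#' Returns the time derivatives `(dv/dt, du/dt)` at a state, including the
#' additive periodic signal. The signal enters only the voltage equation.
#'
#' @param state [izh_state()]
#' @param p [neuron_params()]
#' @param s [signal_params()]; defaults to no signal
#' @return numeric vector `c(dv, du)`
#' @export
izh_flow <- function(state, p, s = signal_params(A = 0)) {
  if (!all(is.finite(c(state$t, state$v, state$u)))) {
    stop("non-finite state: integration blow-up", call. = FALSE)
  }
  v <- state$v
  u <- state$u
  dv <- 0.04 * v^2 + 5 * v + 140 - u + p$I + signal_value(state$t, s)
  du <- p$a * (p$b * v - u)
  c(dv = dv, du = du)
}

#' Jacobian of the flow
#'
#' The variational equations are driven by
#' `J = [[0.08 v + 5, -1], [a b, -a]]`. The additive signal S(t) does not
#' depend on the state, so it does not enter the Jacobian.
#'
#' @param state [izh_state()]
#' @param p [neuron_params()]
#' @return a 2x2 numeric matrix
#' @export
izh_jacobian <- function(state, p) {
  if (!all(is.finite(c(state$v, state$u)))) {
    stop("non-finite state", call. = FALSE)
  }
  matrix(c(0.08 * state$v + 5, p$a * p$b,
           -1, -p$a),
         nrow = 2, ncol = 2)
}

#' Post-spike reset (jump) map
#'
#' When the membrane potential reaches the firing threshold (30 mV), `v` is
#' set to `c` and `u` to `u + d`. Calling this on a sub-threshold state is a
#' contract violation.
#'
#' @param state_pre state at the threshold crossing (`v = 30` within `tol`)
#' @param p [neuron_params()]
#' @param tol threshold tolerance (mV)
#' @return the post-reset [izh_state()] at the same time
#' @export
reset_map <- function(state_pre, p, tol = 1e-6) {
  if (abs(state_pre$v - IZH_THRESHOLD) > tol) {
    stop("reset_map called away from the firing threshold v = 30",
         call. = FALSE)
  }
  izh_state(t = state_pre$t, v = p$c, u = state_pre$u + p$d)
}
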