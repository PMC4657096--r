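#' Sigmoidal activation parameters
#'
#' Slope and center of the static sigmoid that maps a unit's membrane state
#' to a normalized firing rate in (0, 1).
#'
#' @param a Dimensionless central slope, must be positive. Default 4.
#' @param u0 Dimensionless center (the membrane state at which activity is
#'   0.5). Default 1.
#' @return An object of class `sigmoid_params`.
#' @seealso [sigmoid()]
#' @export
#' @examples
#' sp <- sigmoid_params()
#' sigmoid(1, sp)  # 0.5 at the center
sigmoid_params <- function(a = 4, u0 = 1) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("`a` must be a single positive finite number", call. = FALSE)
  if (!is.numeric(u0) || length(u0) != 1L || !is.finite(u0))
    stop("`u0` must be a single finite number", call. = FALSE)
  structure(list(a = a, u0 = u0), class = "sigmoid_params")
}

#' Time-stepping configuration for the leaky-integrator dynamics
#'
#' All populations share a first-order membrane time constant `tau`; the
#' cortical lateral-inhibition state has its own slower constant `tau_L`.
#' Integration is explicit Euler with fixed step `dt`; the step must be at
#' most `tau / 10` so the scheme stays well inside its stability region.
#'
#' @param dt Time step in ms. Default 0.1.
#' @param tau Membrane time constant in ms. Default 10.
#' @param tau_L Lateral-inhibition time constant in ms. Default 50.
#' @return An object of class `integrator_config`.
#' @export
integrator_config <- function(dt = 0.1, tau = 10, tau_L = 50) {
  for (nm in c("dt", "tau", "tau_L")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a single positive finite number", call. = FALSE)
  }
  if (dt > tau / 10)
    stop("`dt` must satisfy dt <= tau/10 (got dt = ", dt, ", tau = ", tau, ")",
         call. = FALSE)
  structure(list(dt = dt, tau = tau, tau_L = tau_L),
            class = "integrator_config")
}

#' Sigmoidal activation function
#'
#' Maps a membrane state to an activity `y = 1 / (1 + exp(-a (u - u0)))`.
#' Strictly increasing, with range (0, 1): the lower threshold and upper
#' saturation of a normalized firing rate. The exponent argument is clamped
#' to +/-500 as a guard against floating-point overflow; the clamp is
#' unreachable in the model's operating range.
#'
#' @param u Membrane state(s); any finite numeric vector.
#' @param p A [sigmoid_params()] object.
#' @return Activities in (0, 1), same length as `u`.
#' @export
sigmoid <- function(u, p = sigmoid_params()) {
  stopifnot(inherits(p, "sigmoid_params"))
  if (!is.numeric(u) || any(!is.finite(u)))
    stop("non-finite membrane state passed to sigmoid(); ",
         "the upstream integration has blown up", call. = FALSE)
  z <- pmin(pmax(-p$a * (u - p$u0), -500), 500)
  1 / (1 + exp(z))
}

#' One explicit Euler step of the membrane equation
#'
#' Advances `tau du/dt = -u + x` by one step:
#' `u' = u + (dt/tau) (x - u)`. The fixed point `u = x` is preserved
#' exactly, and for constant input the iterates follow the discrete
#' exponential relaxation toward `x`.
#'
#' @param u Current membrane state(s).
#' @param x Net input(s), same length as `u` (or scalar).
#' @param tau Time constant in ms, positive.
#' @param dt Step in ms, positive.
#' @return Updated membrane state(s).
#' @export
#' @examples
#' euler_step(0, 1, tau = 10, dt = 1)  # 0.1
euler_step <- function(u, x, tau, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("`tau` must be a single positive number", call. = FALSE)
  u + (dt / tau) * (x - u)
}

#' @export
print.sigmoid_params <- function(x, ...) {
  cat("<sigmoid_params> a =", x$a, ", u0 =", x$u0, "\n")
  invisible(x)
}

#' @export
print.integrator_config <- function(x, ...) {
  cat("<integrator_config> dt =", x$dt, "ms, tau =", x$tau,
      "ms, tau_L =", x$tau_L, "ms\n")
  invisible(x)
}
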