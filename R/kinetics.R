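#' Voltage-dependent gate kinetics
#'
#' Describes a single Hodgkin-Huxley gating variable by its logistic
#' steady-state curve
#' \deqn{x_\infty(V) = 1 / (1 + \exp(-k (V_{1/2} - V)))}
#' and a voltage-dependent time constant in one of two forms:
#' exponential, \eqn{\tau_x(V) = A \exp(k_\tau (V - V_{1/2,\tau}))}, or
#' logistic (saturating at A with depolarization for negative \eqn{k_\tau}),
#' \eqn{\tau_x(V) = A / (1 + \exp(-k_\tau (V_{1/2,\tau} - V)))}.
#'
#' @param k_inf slope of the steady-state curve (1/mV); its sign sets whether
#'   the gate activates (negative) or inactivates (positive) with depolarization.
#' @param v_half_inf half-maximum potential of the steady-state curve (mV).
#' @param a_tau time-constant scale (ms); must be positive.
#' @param k_tau time-constant voltage slope (1/mV).
#' @param v_half_tau time-constant half potential (mV).
#' @param exponent integer power of the gate in the conductance product
#'   (>= 1).
#' @param tau_form `"logistic"` or `"exponential"` time-constant curve.
#' @return An object of class `gate_kinetics`.
#' @export
gate_kinetics <- function(k_inf, v_half_inf, a_tau, k_tau, v_half_tau,
                          exponent = 1L,
                          tau_form = c("logistic", "exponential")) {
  stopifnot(is.numeric(k_inf), is.numeric(v_half_inf),
            is.numeric(a_tau), length(a_tau) == 1L, a_tau > 0,
            is.numeric(k_tau), is.numeric(v_half_tau))
  tau_form <- match.arg(tau_form)
  exponent <- as.integer(exponent)
  if (exponent < 1L) stop("gate exponent must be >= 1")
  structure(list(k_inf = k_inf, v_half_inf = v_half_inf, a_tau = a_tau,
                 k_tau = k_tau, v_half_tau = v_half_tau, exponent = exponent,
                 tau_form = tau_form),
            class = "gate_kinetics")
}

#' Steady-state value of a gate
#'
#' @param v membrane potential (mV); vectorized.
#' @param gk a [gate_kinetics()] object.
#' @return Steady-state open fraction in (0, 1).
#' @export
gate_inf <- function(v, gk) {
  1 / (1 + exp(-gk$k_inf * (gk$v_half_inf - v)))
}

#' Time constant of a gate at temperature
#'
#' The baseline time constant \eqn{\tau(V) = A \exp(k_\tau (V - V_{1/2,\tau}))}
#' is divided by the temperature-sensitivity factor `r`: warming (r > 1)
#' accelerates gating.
#'
#' @param v membrane potential (mV); vectorized.
#' @param gk a [gate_kinetics()] object.
#' @param r temperature-sensitivity factor (dimensionless, > 0); see
#'   [temperature_factor()].
#' @return Time constant in ms.
#' @export
gate_tau <- function(v, gk, r = 1) {
  if (!is.numeric(r) || any(r <= 0)) stop("temperature factor r must be > 0")
  tau0 <- if (identical(gk$tau_form, "exponential")) {
    gk$a_tau * exp(gk$k_tau * (v - gk$v_half_tau))
  } else {
    gk$a_tau / (1 + exp(-gk$k_tau * (gk$v_half_tau - v)))
  }
  tau0 / r
}

#' Q10 temperature-sensitivity factor
#'
#' Converts a Q10 into the multiplicative rate factor at temperature `temp_c`
#' relative to the 10 degree C baseline:
#' \deqn{R = Q_{10}^{(T - 10)/10}}
#' so that R = 1 at 10 C and R = Q10 at 20 C.
#'
#' @param q10 temperature sensitivity (> 0); Q10 = 1 is insensitive.
#' @param temp_c temperature in degrees Celsius; vectorized.
#' @param t_ref reference (baseline) temperature, default 10 C.
#' @return Dimensionless factor R > 0.
#' @export
temperature_factor <- function(q10, temp_c, t_ref = 10) {
  if (any(q10 <= 0)) stop("q10 must be positive")
  q10^((temp_c - t_ref) / 10)
}

#' Default axonal channel gate kinetics
#'
#' The three gates of the fast Sodium (activation m, inactivation h) and
#' delayed-rectifier Potassium (activation n) channels of the model axon.
#' Gate exponents default to the canonical Hodgkin-Huxley powers (m^3 h, n^4);
#' they are configuration fields, not constants of the implementation.
#'
#' The time-constant curves default to the saturating logistic form (the
#' convention of stomatogastric conductance-based models): tau rises towards
#' its ceiling A with depolarization, so Na activation takes 1-2 ms during the
#' upstroke rather than collapsing towards zero as the exponential form would.
#' This choice is calibrated against the model's baseline conduction
#' velocities (see the methods vignette).
#'
#' @param exp_m,exp_h,exp_n integer gate exponents.
#' @param tau_form time-constant curve form for all three gates.
#' @return Named list of three [gate_kinetics()] objects (`m`, `h`, `n`).
#' @export
axon_kinetics <- function(exp_m = 3L, exp_h = 1L, exp_n = 4L,
                          tau_form = c("logistic", "exponential")) {
  tau_form <- match.arg(tau_form)
  list(
    m = gate_kinetics(k_inf = -0.4, v_half_inf = -36, a_tau = 2,
                      k_tau = -0.5, v_half_tau = -40, exponent = exp_m,
                      tau_form = tau_form),
    h = gate_kinetics(k_inf = 1, v_half_inf = -39.5, a_tau = 40,
                      k_tau = -0.025, v_half_tau = -55, exponent = exp_h,
                      tau_form = tau_form),
    n = gate_kinetics(k_inf = -0.125, v_half_inf = -33, a_tau = 55,
                      k_tau = -0.015, v_half_tau = -28, exponent = exp_n,
                      tau_form = tau_form)
  )
}
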