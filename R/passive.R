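#' Fractional passive-membrane parameters
#'
#' A parallel resistor/constant-phase-element membrane: resistance `Rm`
#' (kOhm cm2), fractional capacitance `Cm_alpha` ((uA/mV) ms^alpha per cm2)
#' and order `alpha`.  The generalized time constant enters as
#' \eqn{\tau^\alpha = R_m C_m^\alpha} (ms^alpha); `tau` below is its
#' \eqn{\alpha}-th root in ms.
#'
#' @param Rm membrane resistance (> 0).
#' @param Cm_alpha fractional capacitance (> 0).
#' @param alpha order in (0, 1].
#' @return an object of class `"passive_params"` with derived `tau_alpha`
#'   (= `Rm * Cm_alpha`) and `tau` (= `tau_alpha^(1/alpha)`).
#' @export
passive_params <- function(Rm = 1, Cm_alpha = 1, alpha = 1) {
  check_alpha(alpha)
  stopifnot(Rm > 0, Cm_alpha > 0)
  tau_alpha <- Rm * Cm_alpha
  structure(list(Rm = Rm, Cm_alpha = Cm_alpha, alpha = alpha,
                 tau_alpha = tau_alpha, tau = tau_alpha^(1 / alpha)),
            class = "passive_params")
}

#' Step response of the fractional passive membrane
#'
#' Membrane potential after a current step \eqn{I_m u(t)}:
#' \deqn{V_m(t) = R_m I_m\,[1 - E_{\alpha,1}(-(t/\tau)^\alpha)],}
#' the Mittag-Leffler generalization of the exponential charging curve.
#' For small \eqn{\alpha} the membrane initially charges faster than the
#' \eqn{\alpha=1} exponential, then approaches the steady state
#' \eqn{R_m I_m} more slowly.
#'
#' @param t time (ms), vectorized, `t >= 0`.
#' @param p a [passive_params] object.
#' @param Im step amplitude (uA/cm2).
#' @return membrane potential (mV).
#' @export
step_response <- function(t, p, Im = 1) {
  stopifnot(inherits(p, "passive_params"))
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  p$Rm * Im * (1 - mittag_leffler(p$alpha, 1, -(t / p$tau)^p$alpha))
}

#' Strength-duration curve of the fractional membrane
#'
#' Threshold current for a stimulus of duration `d`:
#' \deqn{I_t = I_{rheo} / [1 - E_{\alpha,1}(-(d/\tau)^\alpha)].}
#' Short durations follow the empirical power law \eqn{d^{-\alpha}}; long
#' durations approach the rheobase.
#'
#' @param d stimulus duration (ms), vectorized, `d > 0`.
#' @param alpha order in (0, 1].
#' @param I_rheo rheobase current (uA/cm2).
#' @param tau membrane time constant (ms).
#' @return threshold current (uA/cm2).
#' @export
strength_duration <- function(d, alpha, I_rheo = 1, tau = 1) {
  check_alpha(alpha)
  if (any(d <= 0)) stop("'d' must be > 0", call. = FALSE)
  I_rheo / (1 - mittag_leffler(alpha, 1, -(d / tau)^alpha))
}

#' Complex impedance of the fractional passive membrane
#'
#' Total impedance of the parallel resistor/constant-phase-element circuit:
#' \deqn{Z(\omega) = \frac{R_m}{1 + R_m (j\omega C_m)^\alpha}.}
#' \eqn{|Z(0)| = R_m}; at high normalized frequency the phase approaches
#' \eqn{-90\alpha} degrees, the constant-phase-element signature.
#'
#' @param omega angular frequency (rad/ms), vectorized, `omega >= 0`.
#' @param p a [passive_params] object.
#' @return complex impedance (kOhm cm2); use `Mod()` and
#'   [impedance_phase] for magnitude and phase.
#' @export
impedance <- function(omega, p) {
  stopifnot(inherits(p, "passive_params"))
  if (any(omega < 0)) stop("'omega' must be >= 0", call. = FALSE)
  jwC <- complex(modulus = omega * p$Cm_alpha, argument = rep(pi / 2, length(omega)))
  out <- p$Rm / (1 + p$Rm * jwC^p$alpha)
  out[omega == 0] <- complex(real = p$Rm, imaginary = 0)
  out
}

#' @rdname impedance
#' @return `impedance_phase`: phase in degrees.
#' @export
impedance_phase <- function(omega, p) {
  Arg(impedance(omega, p)) * 180 / pi
}
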