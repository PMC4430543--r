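#' Parameters of the fractional-order Hodgkin-Huxley membrane patch
#'
#' Standard squid-axon parameters in the rest-relative voltage convention
#' (`v = V_m - V_rest`, depolarization positive): maximal conductances
#' `g_Na = 120`, `g_K = 36`, `g_L = 0.3` mS/cm2 and reversal potentials
#' `E_Na = 115`, `E_K = -12`, `E_L = 10.6` mV.  The fractional capacitance
#' is numerically 1 in uF/cm2-based units, with the ms^(alpha-1) factor
#' absorbed into the units so that `alpha = 1` recovers the classical model
#' without rescaling.
#'
#' @param alpha fractional order of the membrane potential dynamics, (0, 1].
#'   Gating variables always remain first order.
#' @param g_Na,g_K,g_L maximal conductances (mS/cm2).
#' @param E_Na,E_K,E_L reversal potentials (mV, relative to rest).
#' @param conductance_scale length-3 multipliers applied to
#'   `(g_Na, g_K, g_L)`; used by the scaled-conductance control model.
#' @return an object of class `"patch_params"`.
#' @export
patch_params <- function(alpha = 1, g_Na = 120, g_K = 36, g_L = 0.3,
                         E_Na = 115, E_K = -12, E_L = 10.6,
                         conductance_scale = c(1, 1, 1)) {
  check_alpha(alpha)
  stopifnot(g_Na >= 0, g_K >= 0, g_L >= 0, length(conductance_scale) == 3L,
            all(conductance_scale >= 0))
  structure(list(alpha = alpha, g_Na = g_Na, g_K = g_K, g_L = g_L,
                 E_Na = E_Na, E_K = E_K, E_L = E_L,
                 conductance_scale = as.numeric(conductance_scale)),
            class = "patch_params")
}

#' @export
print.patch_params <- function(x, ...) {
  cat(sprintf("fractional-order HH patch: alpha = %g\n", x$alpha))
  cat(sprintf("  g (mS/cm2): Na %.4g  K %.4g  L %.4g   scale: %s\n",
              x$g_Na, x$g_K, x$g_L, paste(signif(x$conductance_scale, 4), collapse = "/")))
  cat(sprintf("  E (mV rel. rest): Na %.4g  K %.4g  L %.4g\n", x$E_Na, x$E_K, x$E_L))
  invisible(x)
}

#' Applied current stimulus
#'
#' Declarative description of the applied current I(t): a brief `pulse`, a
#' constant `step`, a `train` of identical pulses at a fixed inter-pulse
#' interval (used by the refractory-interval search with `n_pulses = 2`), or
#' `none`.
#'
#' @param kind one of `"pulse"`, `"step"`, `"train"`, `"none"`.
#' @param amplitude current density (uA/cm2).
#' @param onset time of onset (ms).
#' @param duration pulse duration (ms); for `step`, the stimulus lasts until
#'   the end of the simulation when `duration = Inf`.
#' @param interval inter-pulse onset-to-onset interval (ms), `train` only.
#' @param n_pulses number of pulses, `train` only.
#' @return an object of class `"fhh_stimulus"`.
#' @export
stimulus <- function(kind = c("pulse", "step", "train", "none"),
                     amplitude = 0, onset = 1, duration = 0.1,
                     interval = 10, n_pulses = 2L) {
  kind <- match.arg(kind)
  if (kind != "none") {
    stopifnot(is.finite(amplitude))
    if (kind != "step" && !(duration > 0)) stop("duration must be > 0", call. = FALSE)
    if (kind == "step" && !(duration > 0)) stop("duration must be > 0", call. = FALSE)
  }
  structure(list(kind = kind, amplitude = amplitude, onset = onset,
                 duration = duration, interval = interval,
                 n_pulses = as.integer(n_pulses)),
            class = "fhh_stimulus")
}

# Evaluate the stimulus on the step grid t_n = n * dt, n = 0..n_steps-1.
stim_vector <- function(stim, dt, n_steps) {
  out <- numeric(n_steps)
  if (stim$kind == "none" || stim$amplitude == 0) return(out)
  t <- (0:(n_steps - 1L)) * dt
  onsets <- switch(stim$kind,
    pulse = stim$onset,
    step = stim$onset,
    train = stim$onset + (0:(stim$n_pulses - 1L)) * stim$interval)
  dur <- if (stim$kind == "step" && !is.finite(stim$duration)) Inf else stim$duration
  for (o in onsets) out[t >= o & t < o + dur] <- stim$amplitude
  out
}

#' Hodgkin-Huxley gating rate functions
#'
#' The six voltage-dependent opening/closing rates of the squid-axon sodium
#' activation (m), sodium inactivation (h), and potassium activation (n)
#' gates, in the rest-relative convention.  The removable singularities at
#' `v = 25` (alpha_m) and `v = 10` (alpha_n) are handled by a series limit.
#'
#' @param v membrane potential (mV relative to rest); vectorized.
#' @return a list with numeric components `alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h`, `alpha_n`, `beta_n` (1/ms).
#' @export
gating_rates <- function(v) {
  stopifnot(is.numeric(v), all(is.finite(v)))
  vtrap <- function(x, y) {
    r <- x / y
    ifelse(abs(r) < 1e-6, y * (1 - r / 2 + r^2 / 12), x / (exp(r) - 1))
  }
  list(alpha_m = 0.1 * vtrap(25 - v, 10),
       beta_m  = 4 * exp(-v / 18),
       alpha_h = 0.07 * exp(-v / 20),
       beta_h  = 1 / (exp((30 - v) / 10) + 1),
       alpha_n = 0.01 * vtrap(10 - v, 10),
       beta_n  = 0.125 * exp(-v / 80))
}

# Resting-state gate values (steady state at v = 0).
rest_gates <- function() {
  r <- gating_rates(0)
  c(m = r$alpha_m / (r$alpha_m + r$beta_m),
    h = r$alpha_h / (r$alpha_h + r$beta_h),
    n = r$alpha_n / (r$alpha_n + r$beta_n))
}

# Assemble the memory-policy arguments for the compiled core.
memory_args <- function(alpha, cfg, n_steps) {
  mem <- resolve_memory(cfg, n_steps)
  if (alpha == 1) {
    # the integer-order scheme is local: truncation at one term is exact
    return(list(policy = 1L, w = 1, L = 1L, K0 = 8L, soe_w = numeric(), soe_rho = numeric(),
                label = "full"))
  }
  if (mem == "full") {
    list(policy = 0L, w = gl_weights(alpha, n_steps + 1L)$weights,
         L = 0L, K0 = 8L, soe_w = numeric(), soe_rho = numeric(), label = "full")
  } else if (mem == "truncated") {
    L <- min(cfg$L, n_steps + 1L)
    list(policy = 1L, w = gl_weights(alpha, L)$weights, L = as.integer(L),
         K0 = 8L, soe_w = numeric(), soe_rho = numeric(), label = "truncated")
  } else {
    K0 <- min(cfg$K0, n_steps + 1L)
    soe <- gl_soe_tail(alpha, K0, n_max = n_steps + 2L)
    list(policy = 2L, w = gl_weights(alpha, K0)$weights, L = 0L,
         K0 = as.integer(K0), soe_w = soe$w, soe_rho = soe$rho, label = "compressed")
  }
}

#' Simulate the fractional-order Hodgkin-Huxley membrane patch
#'
#' Integrates the space-clamped fractional HH model: the membrane potential
#' carries the fractional order `p$alpha` (explicit Grunwald-Letnikov
#' scheme), the gates are first order (forward Euler).  The neuron starts at
#' rest (`v = 0`, gates at their `v = 0` steady state).
#'
#' @param p a [patch_params] object.
#' @param stim an [stimulus] object.
#' @param cfg a [solver_config]; when `cfg$dt` is `NULL` the per-order
#'   default from [default_dt] is used.
#' @return an object of class `"fhh_trajectory"`: time grid (`times`, ms),
#'   membrane potential `v` (mV rel. rest), gates `m`, `h`, `n`, ionic
#'   currents `I_Na`, `I_K`, `I_L` (uA/cm2), and the voltage memory trace
#'   `v_mem` (mV), plus solver metadata.
#' @examples
#' \donttest{
#' tr <- simulate_patch(patch_params(alpha = 1),
#'                      stimulus("step", amplitude = 20, onset = 0),
#'                      solver_config(dt = 0.01, t_end = 40))
#' summary(detect_spikes(tr))
#' }
#' @export
simulate_patch <- function(p = patch_params(),
                           stim = stimulus("none"),
                           cfg = solver_config()) {
  stopifnot(inherits(p, "patch_params"), inherits(stim, "fhh_stimulus"))
  dt <- if (is.null(cfg$dt)) default_dt(p$alpha) else cfg$dt
  n_steps <- as.integer(ceiling(cfg$t_end / dt))
  ma <- memory_args(p$alpha, cfg, n_steps)
  g <- c(p$g_Na, p$g_K, p$g_L) * p$conductance_scale
  res <- cpp_hh_patch(p$alpha, dt, n_steps, stim_vector(stim, dt, n_steps),
                      g, c(p$E_Na, p$E_K, p$E_L), rest_gates(),
                      ma$policy, ma$w, ma$L, ma$K0, ma$soe_w, ma$soe_rho,
                      cfg$record_stride)
  times <- seq(0L, n_steps, by = cfg$record_stride) * dt
  structure(c(list(times = times), res,
              list(alpha = p$alpha, dt = dt, params = p, stimulus = stim,
                   memory = ma$label)),
            class = "fhh_trajectory")
}

#' @export
print.fhh_trajectory <- function(x, ...) {
  cat(sprintf("fHH trajectory: alpha = %g, dt = %g ms, %d samples over %.4g ms (%s memory)\n",
              x$alpha[1], x$dt, length(x$times), max(x$times), x$memory))
  if (!is.null(x$v) && is.null(dim(x$v)))
    cat(sprintf("  v range: [%.3g, %.3g] mV\n", min(x$v), max(x$v)))
  invisible(x)
}

#' @export
summary.fhh_trajectory <- function(object, ...) {
  v <- object$v
  if (!is.null(dim(v))) v <- v[, 1L]
  sp <- detect_spikes(object)
  out <- list(alpha = object$alpha[1], dt = object$dt,
              t_end = max(object$times), v_max = max(v), v_min = min(v),
              n_spikes = length(sp$peak_times))
  class(out) <- "summary.fhh_trajectory"
  out
}

#' @export
print.summary.fhh_trajectory <- function(x, ...) {
  cat(sprintf("alpha = %g, dt = %g ms, duration %.4g ms\n", x$alpha, x$dt, x$t_end))
  cat(sprintf("v in [%.3g, %.3g] mV; %d spike(s)\n", x$v_min, x$v_max, x$n_spikes))
  invisible(x)
}

#' @export
plot.fhh_trajectory <- function(x, what = c("v", "currents", "v_mem"), ...) {
  what <- match.arg(what)
  if (what == "v") {
    v <- x$v
    if (!is.null(dim(v))) {
      graphics::matplot(x$times, v, type = "l", lty = 1,
                        xlab = "time (ms)", ylab = "v (mV rel. rest)", ...)
    } else {
      graphics::plot(x$times, v, type = "l",
                     xlab = "time (ms)", ylab = "v (mV rel. rest)", ...)
    }
  } else if (what == "currents") {
    graphics::matplot(x$times, cbind(x$I_Na, x$I_K, x$I_L), type = "l", lty = 1,
                      col = c(2, 4, 3), xlab = "time (ms)", ylab = "I (uA/cm2)", ...)
    graphics::legend("topright", c("I_Na", "I_K", "I_L"), col = c(2, 4, 3), lty = 1, bty = "n")
  } else {
    graphics::plot(x$times, x$v_mem, type = "l",
                   xlab = "time (ms)", ylab = "v_mem (mV)", ...)
  }
  invisible(x)
}

#' @rdname simulate_patch
#' @param object a [patch_params] object (S3 `simulate` method).
#' @param nsim,seed ignored (the patch model is deterministic); present for
#'   compatibility with the [stats::simulate] generic.
#' @param ... passed on: `stim`, `cfg`.
#' @export
simulate.patch_params <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_patch(object, ...)
}
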