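#' Spatial grid for the fractional nerve axon
#'
#' A 1-cm cable discretized by the method of lines at `dx = 0.05` cm
#' (0.5 mm), with sealed (zero-flux) ends.  The longitudinal conductance `g`
#' (uS) enters the discrete voltage-diffusion current as
#' `g * (v[i+1] - 2 v[i] + v[i-1]) / dx^2` with `dx` in cm, giving a
#' conductance-density-scale coupling coefficient `g/dx^2` (mS/cm2 for the
#' default values) under which the first-order cable propagates at a
#' physiological velocity.
#'
#' @param length cable length (cm).
#' @param dx spatial step (cm); `length/dx` must be a whole number.
#' @param g_axial longitudinal conductance (uS); reference values 7.06 and
#'   0.706.
#' @return an object of class `"cable_grid"` with derived `n_nodes` and `x`
#'   (node positions, cm).
#' @export
cable_grid <- function(length = 1, dx = 0.05, g_axial = 7.06) {
  stopifnot(length > 0, dx > 0, g_axial > 0)
  n_int <- length / dx
  if (abs(n_int - round(n_int)) > 1e-8)
    stop("length/dx must be an integer", call. = FALSE)
  n_nodes <- as.integer(round(n_int)) + 1L
  structure(list(length = length, dx = dx, g_axial = g_axial,
                 boundary = "sealed", n_nodes = n_nodes,
                 x = seq(0, length, by = dx)),
            class = "cable_grid")
}

#' Simulate the fractional-order Hodgkin-Huxley cable
#'
#' Active nerve axon: the fractional HH equations at every node plus a
#' voltage diffusion term, integrated by the method of lines with the
#' explicit GL scheme (fractional order on every node's `v`, first order on
#' the gates).  The stimulus is applied at `x = 0` unless
#' `uniform_stimulus = TRUE` (all nodes; the diffusion term then vanishes
#' and every node reproduces the patch trajectory).
#'
#' @param p a [patch_params] object.
#' @param grid a [cable_grid] object.
#' @param stim an [stimulus] object, applied at `x = 0`.
#' @param cfg a [solver_config].
#' @param uniform_stimulus apply the stimulus to every node.
#' @param conductance_scale_nodes optional `n_nodes x 3` matrix of per-node
#'   multipliers of `(g_Na, g_K, g_L)` (scaled-conductance control).
#' @return an object of class `c("fhh_cable_trajectory", "fhh_trajectory")`:
#'   `times` (ms), `v` (matrix, rows = recorded times, cols = nodes), `x`
#'   (node positions, cm), per-node peak current magnitudes `peak_I_Na`,
#'   `peak_I_K`, maximum depolarizing leak `peak_I_L_dep`, and `peak_v_mem`.
#' @export
simulate_cable <- function(p, grid = cable_grid(), stim = stimulus("pulse", amplitude = 500),
                           cfg = solver_config(t_end = 15),
                           uniform_stimulus = FALSE,
                           conductance_scale_nodes = NULL) {
  stopifnot(inherits(p, "patch_params"), inherits(grid, "cable_grid"))
  dt <- if (is.null(cfg$dt)) default_dt(p$alpha) else cfg$dt
  n_steps <- as.integer(ceiling(cfg$t_end / dt))
  D <- grid$g_axial * 1e-3 / grid$dx^2   # uS -> mS, per dx^2 in cm^2
  cfl <- D * dt^p$alpha
  if (cfl > 0.5)
    warning(sprintf("diffusion stability number g*dt^alpha/dx^2 = %.3g; consider a smaller dt", cfl))
  gb <- matrix(rep(c(p$g_Na, p$g_K, p$g_L) * p$conductance_scale,
                   each = grid$n_nodes), grid$n_nodes, 3L)
  if (!is.null(conductance_scale_nodes)) {
    stopifnot(is.matrix(conductance_scale_nodes),
              nrow(conductance_scale_nodes) == grid$n_nodes,
              ncol(conductance_scale_nodes) == 3L)
    gb <- gb * conductance_scale_nodes
  }
  stim_nodes <- if (uniform_stimulus) 0:(grid$n_nodes - 1L) else 0L
  ma <- memory_args(p$alpha, cfg, n_steps)
  res <- cpp_hh_cable(p$alpha, dt, n_steps, grid$n_nodes,
                      stim_vector(stim, dt, n_steps), as.integer(stim_nodes),
                      gb, c(p$E_Na, p$E_K, p$E_L), rest_gates(), D,
                      ma$policy, ma$w, ma$L, ma$K0, ma$soe_w, ma$soe_rho,
                      cfg$record_stride)
  times <- seq(0L, n_steps, by = cfg$record_stride) * dt
  structure(c(list(times = times), res,
              list(x = grid$x, alpha = p$alpha, dt = dt, params = p,
                   grid = grid, stimulus = stim, memory = ma$label)),
            class = c("fhh_cable_trajectory", "fhh_trajectory"))
}

#' Spike propagation velocity from a space-time trajectory
#'
#' Velocity per propagating spike from the peak times at two probe
#' positions (defaults `x = 0.25` and `0.75` cm):
#' `velocity_i = (x2 - x1) / (t_peak_i(x2) - t_peak_i(x1))`.  Spikes are
#' paired by ordinal index; trailing spikes seen at the proximal but not the
#' distal probe flag propagation failure.
#'
#' @param traj an `fhh_cable_trajectory`.
#' @param probes the two probe positions (cm).
#' @param ... passed to [detect_spikes].
#' @return an object of class `"velocity_series"`: `spike_index`, `velocity`
#'   (cm/ms), `pct_change_from_final` (%), `n_failed` (spikes at the
#'   proximal probe that never arrived distally), and the probe peak times.
#' @export
measure_velocity <- function(traj, probes = c(0.25, 0.75), ...) {
  stopifnot(inherits(traj, "fhh_cable_trajectory"))
  idx <- vapply(probes, function(px) which.min(abs(traj$x - px)), integer(1))
  sp1 <- detect_spikes(traj$v[, idx[1]], traj$times, ...)
  sp2 <- detect_spikes(traj$v[, idx[2]], traj$times, ...)
  if (!length(sp1$peak_times))
    stop("no spikes detected at the proximal probe", call. = FALSE)
  n_pair <- min(length(sp1$peak_times), length(sp2$peak_times))
  t1 <- sp1$peak_times[seq_len(n_pair)]
  t2 <- sp2$peak_times[seq_len(n_pair)]
  if (n_pair && (any(t2 <= t1) || (n_pair > 1L && any(diff(t2) <= 0))))
    stop("non-monotone peak pairing between probes", call. = FALSE)
  dx <- abs(traj$x[idx[2]] - traj$x[idx[1]])
  vel <- dx / (t2 - t1)
  pct <- if (n_pair) 100 * (vel - vel[n_pair]) / vel[n_pair] else numeric(0)
  structure(list(spike_index = seq_len(n_pair), velocity = vel,
                 pct_change_from_final = pct,
                 n_failed = length(sp1$peak_times) - n_pair,
                 t_proximal = sp1$peak_times, t_distal = sp2$peak_times),
            class = "velocity_series")
}

#' @export
print.velocity_series <- function(x, ...) {
  cat(sprintf("propagation velocity: %d paired spike(s)", length(x$spike_index)))
  if (x$n_failed) cat(sprintf(" (+%d failed to propagate)", x$n_failed))
  cat("\n")
  if (length(x$velocity))
    cat("  velocity (cm/ms):", paste(signif(x$velocity, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Per-spike velocities during a constant stimulus
#'
#' Runs the cable with a constant current at `x = 0` and returns the
#' per-spike propagation velocities, the asymptotic (final fully
#' propagating) velocity, and the ordinal of the first spike that failed to
#' propagate (if any).
#'
#' @param p a [patch_params] object.
#' @param grid a [cable_grid].
#' @param I_app constant current amplitude (uA/cm2).
#' @param cfg a [solver_config].
#' @param ... passed to [measure_velocity].
#' @return the [measure_velocity] result with extra fields `asymptotic`
#'   (cm/ms) and `first_failed_spike` (`NA` if all propagate).
#' @export
constant_stimulus_velocity_series <- function(p, grid = cable_grid(), I_app = 20,
                                              cfg = solver_config(t_end = 100), ...) {
  traj <- simulate_cable(p, grid, stimulus("step", amplitude = I_app, onset = 0,
                                           duration = Inf), cfg)
  vs <- measure_velocity(traj, ...)
  vs$asymptotic <- if (length(vs$velocity)) vs$velocity[length(vs$velocity)] else NA_real_
  vs$first_failed_spike <- if (vs$n_failed) length(vs$spike_index) + 1L else NA_integer_
  vs
}
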