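#' Detect spikes in a voltage trace
#'
#' Spikes are local maxima of the membrane potential above `threshold`,
#' separated by at least `min_separation`.  Peak times are refined by
#' parabolic interpolation of the three samples around each maximum, so the
#' timing resolution is much finer than the recording grid.  The spike
#' criterion (40 mV, 2 ms) is an operational choice exposed here as
#' arguments.
#'
#' @param traj an `fhh_trajectory`, or a numeric voltage vector.
#' @param times time grid (ms); only needed when `traj` is a bare vector.
#' @param threshold detection threshold (mV relative to rest).
#' @param min_separation minimum peak separation (ms).
#' @return an object of class `"fhh_spikes"`: `peak_times` (ms),
#'   `peak_values` (mV), `isi` (ms), and `inst_freq` (`1000/isi`, Hz).
#'   An empty train is allowed.
#' @export
detect_spikes <- function(traj, times = NULL, threshold = 40, min_separation = 2) {
  if (inherits(traj, "fhh_trajectory")) {
    v <- traj$v
    if (!is.null(dim(v))) stop("for space-time trajectories, pass a single node's trace", call. = FALSE)
    times <- traj$times
  } else {
    v <- as.numeric(traj)
    if (is.null(times)) stop("'times' required for a bare voltage vector", call. = FALSE)
  }
  n <- length(v)
  pk_t <- numeric(0); pk_v <- numeric(0)
  if (n >= 3L) {
    i <- which(v[2:(n - 1L)] >= v[1:(n - 2L)] & v[2:(n - 1L)] > v[3:n] &
                 v[2:(n - 1L)] > threshold) + 1L
    if (length(i)) {
      # enforce min separation, keeping the larger peak of any close pair
      ord <- i[order(v[i], decreasing = TRUE)]
      keep <- logical(0); kept_t <- numeric(0)
      for (j in ord) {
        tj <- times[j]
        if (!length(kept_t) || all(abs(kept_t - tj) >= min_separation)) {
          keep <- c(keep, j); kept_t <- c(kept_t, tj)
        }
      }
      i <- sort(keep)
      for (j in i) {
        y1 <- v[j - 1L]; y2 <- v[j]; y3 <- v[j + 1L]
        denom <- y1 - 2 * y2 + y3
        delta <- if (abs(denom) > 1e-300) 0.5 * (y1 - y3) / denom else 0
        delta <- max(-0.5, min(0.5, delta))
        h <- times[j + 1L] - times[j]
        pk_t <- c(pk_t, times[j] + delta * h)
        pk_v <- c(pk_v, y2 - 0.25 * (y1 - y3) * delta)
      }
    }
  }
  isi <- diff(pk_t)
  structure(list(peak_times = pk_t, peak_values = pk_v,
                 isi = isi, inst_freq = if (length(isi)) 1000 / isi else numeric(0)),
            class = "fhh_spikes")
}

#' @export
print.fhh_spikes <- function(x, ...) {
  cat(sprintf("spike train: %d spike(s)\n", length(x$peak_times)))
  if (length(x$peak_times)) {
    cat("  peaks (ms):", paste(signif(utils::head(x$peak_times, 8), 5), collapse = ", "))
    if (length(x$peak_times) > 8) cat(", ...")
    cat("\n")
    if (length(x$inst_freq))
      cat(sprintf("  inst. frequency (Hz): first %.4g, last %.4g\n",
                  x$inst_freq[1], x$inst_freq[length(x$inst_freq)]))
  }
  invisible(x)
}

#' @export
summary.fhh_spikes <- function(object, ...) {
  cat(sprintf("%d spike(s)", length(object$peak_times)))
  if (length(object$isi))
    cat(sprintf("; mean ISI %.4g ms; mean inst. frequency %.4g Hz",
                mean(object$isi), mean(object$inst_freq)))
  cat("\n")
  invisible(object)
}

#' Brief-pulse spike threshold
#'
#' Locates the threshold amplitude of a brief pulse (default 0.1 ms) that
#' elicits a spike, by bisection on the pulse amplitude to 0.5 uA/cm2
#' resolution.  The upper bracket starts at 100 uA/cm2 and doubles up to
#' 5000; if the largest bracket still fails to elicit a spike an error is
#' raised.
#'
#' @param p a [patch_params] object (its `alpha` is used).
#' @param pulse_duration pulse width (ms).
#' @param cfg optional [solver_config]; defaults to a 20-ms run at the
#'   per-order default time step.
#' @param resolution bisection resolution (uA/cm2).
#' @return threshold amplitude (uA/cm2).
#' @export
find_threshold <- function(p, pulse_duration = 0.1, cfg = NULL, resolution = 0.5) {
  stopifnot(inherits(p, "patch_params"))
  if (is.null(cfg)) cfg <- solver_config(dt = default_dt(p$alpha), t_end = 20)
  spikes_at <- function(amp) {
    tr <- simulate_patch(p, stimulus("pulse", amplitude = amp, onset = 1,
                                     duration = pulse_duration), cfg)
    length(detect_spikes(tr)$peak_times)
  }
  lo <- 0; hi <- 100
  while (spikes_at(hi) < 1L) {
    lo <- hi; hi <- 2 * hi
    if (hi > 5000) stop("no spike at the 5000 uA/cm2 upper bracket", call. = FALSE)
  }
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid) >= 1L) hi <- mid else lo <- mid
  }
  hi
}

#' Post-spike refractory interval
#'
#' Minimum inter-stimulus interval at which two brief pulses (1.5x threshold,
#' 0.1 ms) trigger two spikes, found by bisection to `resolution` (default
#' 0.05 ms).  Also returns the time from the first stimulus onset to the
#' first spike peak and the difference between the two, which measures
#' refractoriness net of the order-dependent latency shift of the spike peak.
#'
#' @param p a [patch_params] object.
#' @param pulse_duration pulse width (ms).
#' @param resolution bisection resolution on the interval (ms).
#' @param cfg optional [solver_config] template (its `dt`/memory policy are
#'   reused; `t_end` adapts to the interval probed).
#' @return list with `min_interstimulus` (ms), `time_to_peak` (ms), and
#'   `difference` (ms) = `min_interstimulus - time_to_peak`.
#' @export
refractory_interval <- function(p, pulse_duration = 0.1, resolution = 0.05, cfg = NULL) {
  stopifnot(inherits(p, "patch_params"))
  dt <- if (!is.null(cfg) && !is.null(cfg$dt)) cfg$dt else default_dt(p$alpha)
  mem <- if (!is.null(cfg)) cfg$memory else "auto"
  thr <- find_threshold(p, pulse_duration,
                        solver_config(dt = dt, t_end = 20, memory = mem))
  amp <- 1.5 * thr
  one <- simulate_patch(p, stimulus("pulse", amplitude = amp, onset = 1,
                                    duration = pulse_duration),
                        solver_config(dt = dt, t_end = 25, memory = mem))
  sp1 <- detect_spikes(one)
  if (!length(sp1$peak_times)) stop("no spike at 1.5x threshold", call. = FALSE)
  t_peak <- sp1$peak_times[1] - 1   # relative to stimulus onset
  two_spikes <- function(interval) {
    tr <- simulate_patch(p, stimulus("train", amplitude = amp, onset = 1,
                                     duration = pulse_duration,
                                     interval = interval, n_pulses = 2L),
                         solver_config(dt = dt, t_end = interval + 22, memory = mem))
    length(detect_spikes(tr)$peak_times) >= 2L
  }
  lo <- max(2 * pulse_duration, 0.5); hi <- 20
  while (!two_spikes(hi)) {
    lo <- hi; hi <- 2 * hi
    if (hi > 200) stop("no second spike at a 200-ms interval", call. = FALSE)
  }
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (two_spikes(mid)) hi <- mid else lo <- mid
  }
  list(min_interstimulus = hi, time_to_peak = t_peak, difference = hi - t_peak)
}

#' Asymptotic repetitive-firing statistics
#'
#' Spike statistics over the final window of a constant-stimulus run
#' (default: final 30 ms of a 100-ms simulation): count-based and mean
#' instantaneous frequency, mean spike amplitude (per-cycle `v_max - v_min`),
#' peak current magnitudes, and the sodium inactivation gate at the times of
#' peak sodium current (`h_peak`).
#'
#' @param traj an `fhh_trajectory` from a constant-stimulus patch run.
#' @param window length of the terminal analysis window (ms).
#' @return list with `freq` (Hz, `(spike count - 1)/span` over the window; 0
#'   with `spiking = FALSE` when fewer than 2 spikes fall in the window),
#'   `freq_inst` (mean instantaneous frequency in the window), `amplitude`
#'   (mV), `peak_I_Na`, `peak_I_K` (magnitudes), `peak_I_L_dep` (maximum
#'   depolarizing leak current), `h_peak`, `spiking`, and `inst_freq_series`
#'   (the whole-run instantaneous frequency per ISI).
#' @export
asymptotic_spike_stats <- function(traj, window = 30) {
  stopifnot(inherits(traj, "fhh_trajectory"))
  sp <- detect_spikes(traj)
  t_end <- max(traj$times)
  t0 <- t_end - window
  inw <- sp$peak_times >= t0
  out <- list(freq = 0, freq_inst = NA_real_, amplitude = NA_real_,
              peak_I_Na = NA_real_, peak_I_K = NA_real_, peak_I_L_dep = NA_real_,
              h_peak = NA_real_, spiking = FALSE,
              inst_freq_series = sp$inst_freq)
  sel <- traj$times >= t0
  out$peak_I_Na <- max(abs(traj$I_Na[sel]))
  out$peak_I_K <- max(abs(traj$I_K[sel]))
  out$peak_I_L_dep <- max(-traj$I_L[sel])   # depolarizing leak is inward
  if (sum(inw) >= 2L) {
    pts <- sp$peak_times[inw]
    out$freq <- 1000 * (length(pts) - 1L) / (pts[length(pts)] - pts[1])
    isiw <- diff(pts)
    out$freq_inst <- mean(1000 / isiw)
    out$spiking <- TRUE
    # per-cycle amplitude: max minus min of v between consecutive peaks
    amps <- vapply(seq_len(length(pts) - 1L), function(i) {
      seg <- traj$times >= pts[i] - 0.5 & traj$times <= pts[i + 1L] + 0.5
      max(traj$v[seg]) - min(traj$v[seg])
    }, numeric(1))
    out$amplitude <- mean(amps)
    # h at the times of peak |I_Na| within each cycle
    hpk <- vapply(seq_along(pts), function(i) {
      lo <- if (i == 1L) max(t0, pts[i] - 5) else pts[i - 1L]
      seg <- which(traj$times >= lo & traj$times <= pts[i] + 1)
      traj$h[seg[which.max(abs(traj$I_Na[seg]))]]
    }, numeric(1))
    out$h_peak <- mean(hpk)
  } else {
    out$amplitude <- max(traj$v[sel]) - min(traj$v[sel])
  }
  out
}

#' First-to-asymptotic instantaneous frequency increase
#'
#' Convenience wrapper: last minus first instantaneous spike frequency
#' (1000/ISI) of a constant-stimulus run.
#'
#' @param traj an `fhh_trajectory`.
#' @return frequency increase (Hz); `NA` with fewer than 2 ISIs.
#' @export
frequency_increase <- function(traj) {
  f <- detect_spikes(traj)$inst_freq
  if (length(f) < 2L) return(NA_real_)
  f[length(f)] - f[1]
}

#' Repetitive-firing current range
#'
#' Sweeps the constant applied current and finds the lower and upper critical
#' currents I1 and I2 between which the neuron fires repetitively ("spiking"
#' means at least 2 spikes in the final `window` ms of a `t_end`-ms run).
#' Grid boundaries are refined by bisection to `refine` resolution.
#'
#' @param p a [patch_params] object.
#' @param I_grid currents to sweep (uA/cm2).
#' @param cfg optional [solver_config].
#' @param window terminal window (ms) used for the spiking classification.
#' @param refine bisection resolution at the boundaries (uA/cm2).
#' @return list with `I1`, `I2` (uA/cm2, `NA` with `found = FALSE` if no grid
#'   point spikes) and `found`.
#' @export
spiking_range <- function(p, I_grid = seq(2, 200, by = 2), cfg = NULL,
                          window = 30, refine = 0.5) {
  stopifnot(inherits(p, "patch_params"))
  if (is.null(cfg)) cfg <- solver_config(dt = default_dt(p$alpha), t_end = 100)
  spiking <- function(I) {
    tr <- simulate_patch(p, stimulus("step", amplitude = I, onset = 0, duration = Inf), cfg)
    asymptotic_spike_stats(tr, window)$spiking
  }
  flags <- vapply(I_grid, spiking, logical(1))
  if (!any(flags)) return(list(I1 = NA_real_, I2 = NA_real_, found = FALSE))
  lo_idx <- which(flags)[1]; hi_idx <- which(flags)[sum(flags)]
  I1 <- I_grid[lo_idx]
  if (lo_idx > 1L) {
    # bisect onto the lowest spiking current
    a <- I_grid[lo_idx - 1L]; b <- I_grid[lo_idx]
    while (b - a > refine) {
      mid <- (a + b) / 2
      if (spiking(mid)) b <- mid else a <- mid
    }
    I1 <- b
  }
  I2 <- I_grid[hi_idx]
  if (hi_idx < length(I_grid)) {
    # bisect onto the highest spiking current
    a <- I_grid[hi_idx]; b <- I_grid[hi_idx + 1L]
    while (b - a > refine) {
      mid <- (a + b) / 2
      if (spiking(mid)) a <- mid else b <- mid
    }
    I2 <- a
  }
  list(I1 = I1, I2 = I2, found = TRUE)
}
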