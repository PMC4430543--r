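#' Generate a random network architecture
#'
#' Random connectivity of `N` neurons: the indegree of each neuron is drawn
#' from a Gaussian with mean `mu` and standard deviation `sigma`, rounded
#' and clipped to `[0, N]`; presynaptic indices are drawn uniformly from
#' `1..N` (self-connections and duplicates are allowed and counted); each
#' synapse is excitatory with probability `p_exc`, otherwise inhibitory.
#' Fully reproducible from `seed`.
#'
#' @param N neuron count.
#' @param mu,sigma indegree mean and standard deviation.
#' @param p_exc probability that a synapse is excitatory.
#' @param seed integer seed for the architecture draw.
#' @return an object of class `"network_spec"`: per-neuron presynaptic index
#'   lists `S_ex` and `S_in`, plus the generation parameters and
#'   `n_self_loops`.
#' @export
generate_network <- function(N = 50L, mu = 25, sigma = 2.5, p_exc = 0.1, seed = 1L) {
  stopifnot(N >= 1, sigma >= 0, p_exc >= 0, p_exc <= 1)
  if (mu > N) stop("mean indegree cannot exceed N", call. = FALSE)
  N <- as.integer(N)
  rng <- local_rng(seed)
  on.exit(rng())
  indeg <- pmin(pmax(round(stats::rnorm(N, mu, sigma)), 0), N)
  S_ex <- vector("list", N); S_in <- vector("list", N)
  n_self <- 0L
  for (i in seq_len(N)) {
    k <- indeg[i]
    pre <- if (k > 0) sample.int(N, k, replace = TRUE) else integer(0)
    n_self <- n_self + sum(pre == i)
    exc <- stats::runif(k) < p_exc
    S_ex[[i]] <- pre[exc]
    S_in[[i]] <- pre[!exc]
  }
  structure(list(N = N, mu = mu, sigma = sigma, p_exc = p_exc, seed = seed,
                 S_ex = S_ex, S_in = S_in, indegree = indeg,
                 n_self_loops = n_self),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("random network: N = %d, mean indegree %.3g (drawn mu = %g, sigma = %g), p_exc = %g, seed = %d\n",
              x$N, mean(x$indegree), x$mu, x$sigma, x$p_exc, x$seed))
  if (x$n_self_loops) cat(sprintf("  %d self-connection(s) present\n", x$n_self_loops))
  invisible(x)
}

# Run code under a private RNG stream seeded by `seed`; returns the restore fn.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Synaptic parameters
#'
#' Instantaneous sigmoidal synapses: the postsynaptic conductance gate is a
#' logistic function of the presynaptic potential with threshold `V_syn` and
#' slope `k_syn`.  The default constants are documented stand-ins.  `g_syn`
#' is set to the smallest round value at which the first-order (alpha = 1)
#' reference network shows self-sustained recurrent activity after the
#' stimulus ends; below about 0.15 mS/cm2 the sparse excitatory connectivity
#' (10% of synapses) cannot regenerate activity and every network dies out
#' at stimulus offset regardless of order.  Network-level results with these
#' stand-ins are interpreted as trends, not calibrated values.
#'
#' @param g_syn synaptic conductance (mS/cm2).
#' @param E_syn_ex,E_syn_in excitatory/inhibitory reversal potentials
#'   (mV rel. rest).
#' @param V_syn gating threshold (mV).
#' @param k_syn gating slope (mV), > 0.
#' @return an object of class `"synapse_params"`.
#' @export
synapse_params <- function(g_syn = 0.15, E_syn_ex = 70, E_syn_in = -12,
                           V_syn = 20, k_syn = 2) {
  stopifnot(k_syn > 0, E_syn_in < V_syn, V_syn < E_syn_ex)
  structure(list(g_syn = g_syn, E_syn_ex = E_syn_ex, E_syn_in = E_syn_in,
                 V_syn = V_syn, k_syn = k_syn),
            class = "synapse_params")
}

#' Synaptic gating function
#'
#' Logistic gate of the postsynaptic conductance,
#' \eqn{s(v) = 1/(1+\exp[-(v - V_{syn})/k_{syn}])}: 0.5 at the threshold,
#' approaching 0/1 at hyper-/depolarized presynaptic potentials.
#'
#' @param v_pre presynaptic membrane potential (mV rel. rest), vectorized.
#' @param sp a [synapse_params] object.
#' @return gate value in (0, 1).
#' @export
synaptic_gate <- function(v_pre, sp = synapse_params()) {
  1 / (1 + exp(-(v_pre - sp$V_syn) / sp$k_syn))
}

#' Simulate a random fractional-order Hodgkin-Huxley network
#'
#' Each neuron follows the fractional HH patch equations plus excitatory and
#' inhibitory synaptic currents with instantaneous sigmoidal gating summed
#' over its presynaptic sets.  Activity is evoked by a constant current in
#' `n_stim` randomly selected neurons during the first `stim_duration` ms.
#'
#' @param net a [generate_network] architecture.
#' @param sp a [synapse_params] object.
#' @param p a [patch_params] object (shared by all neurons).
#' @param cfg a [solver_config]; 550 ms by default.
#' @param stim_amplitude stimulus current (uA/cm2).
#' @param stim_duration stimulus duration (ms).
#' @param n_stim number of stimulated neurons.
#' @param stim_seed seed for the stimulated-neuron draw.
#' @param spike_threshold,min_separation passed to [detect_spikes].
#' @return an object of class `"fhh_network_summary"`: `raster` (data frame
#'   `neuron`, `time`), `pEEG` (network-mean potential, mV), `times`,
#'   network-averaged `I_synE`/`I_synI` series, `firing_rate` (from
#'   [firing_rate]), `isi` (all ISIs pooled over neurons),
#'   `activity_duration` (ms, last spike time; 0 if silent), `sustained`
#'   (any spike in the final 50 ms), and synaptic charges `Q_synE`,
#'   `Q_synI` (uA ms/cm2 magnitudes over the stimulus window).
#' @export
simulate_network <- function(net, sp = synapse_params(), p = patch_params(),
                             cfg = solver_config(t_end = 550),
                             stim_amplitude = 40, stim_duration = 50,
                             n_stim = 13L, stim_seed = 1L,
                             spike_threshold = 40, min_separation = 2) {
  stopifnot(inherits(net, "network_spec"), inherits(sp, "synapse_params"),
            inherits(p, "patch_params"))
  dt <- if (is.null(cfg$dt)) default_dt(p$alpha) else cfg$dt
  n_steps <- as.integer(ceiling(cfg$t_end / dt))
  stride <- cfg$record_stride
  rng <- local_rng(stim_seed)
  stim_neurons <- sample.int(net$N, min(n_stim, net$N))
  rng()
  # CSR adjacency (0-based) for the compiled core
  csr <- function(lst) {
    lens <- vapply(lst, length, integer(1))
    list(ptr = as.integer(c(0L, cumsum(lens))),
         idx = as.integer(unlist(lst, use.names = FALSE) - 1L))
  }
  ex <- csr(net$S_ex); inh <- csr(net$S_in)
  ma <- memory_args(p$alpha, cfg, n_steps)
  g <- c(p$g_Na, p$g_K, p$g_L) * p$conductance_scale
  res <- cpp_hh_network(p$alpha, dt, n_steps, net$N,
                        ex$ptr, ex$idx, inh$ptr, inh$idx,
                        c(sp$g_syn, sp$E_syn_ex, sp$E_syn_in, sp$V_syn, sp$k_syn),
                        as.integer(stim_neurons - 1L), stim_amplitude,
                        as.integer(ceiling(stim_duration / dt)),
                        g, c(p$E_Na, p$E_K, p$E_L), rest_gates(),
                        ma$policy, ma$w, ma$L, ma$K0, ma$soe_w, ma$soe_rho, stride)
  times <- seq(0L, n_steps, by = stride) * dt
  spikes <- lapply(seq_len(net$N), function(i)
    detect_spikes(res$v[, i], times, spike_threshold, min_separation)$peak_times)
  raster <- data.frame(neuron = rep(seq_len(net$N), vapply(spikes, length, integer(1))),
                       time = unlist(spikes, use.names = FALSE))
  raster <- raster[order(raster$time, raster$neuron), , drop = FALSE]
  rownames(raster) <- NULL
  all_isi <- unlist(lapply(spikes, function(tt) if (length(tt) > 1L) diff(tt) else numeric(0)),
                    use.names = FALSE)
  dur <- if (nrow(raster)) max(raster$time) else 0
  qs <- synaptic_charge(res$I_synE, res$I_synI, times, window = stim_duration)
  structure(list(raster = raster, pEEG = rowMeans(res$v), times = times,
                 I_synE = res$I_synE, I_synI = res$I_synI,
                 firing_rate = firing_rate(raster, net$N, t_end = cfg$t_end),
                 isi = all_isi, activity_duration = dur,
                 sustained = any(raster$time > cfg$t_end - 50),
                 Q_synE = qs[1], Q_synI = qs[2],
                 alpha = p$alpha, dt = dt, stim_neurons = sort(stim_neurons),
                 memory = ma$label),
            class = "fhh_network_summary")
}

#' @export
print.fhh_network_summary <- function(x, ...) {
  cat(sprintf("fHH network (alpha = %g): %d spikes, activity duration %.4g ms, %s\n",
              x$alpha, nrow(x$raster), x$activity_duration,
              if (x$sustained) "sustained" else "self-terminated"))
  cat(sprintf("  Q_synE = %.4g, Q_synI = %.4g uA ms/cm2\n", x$Q_synE, x$Q_synI))
  invisible(x)
}

#' Sliding-window firing rate
#'
#' Spikes per neuron in sliding windows (default 50 ms, stepped by 10 ms),
#' windows clipped at the simulation bounds.
#'
#' @param raster data frame with columns `neuron`, `time`, or a numeric
#'   vector of spike times.
#' @param N neuron count (the denominator).
#' @param window,step window length and step (ms).
#' @param t_end simulation length (ms).
#' @return data frame with `t_mid` (window midpoint, ms) and `rate`
#'   (spikes/neuron/window).
#' @export
firing_rate <- function(raster, N, window = 50, step = 10, t_end = NULL) {
  times <- if (is.data.frame(raster)) raster$time else as.numeric(raster)
  if (is.null(t_end)) t_end <- if (length(times)) max(times) else window
  starts <- seq(0, max(0, t_end - window), by = step)
  rate <- vapply(starts, function(s)
    sum(times >= s & times < s + window) / N, numeric(1))
  data.frame(t_mid = starts + window / 2, rate = rate)
}

#' Synaptic charge over the stimulus window
#'
#' Trapezoidal time integral of the network-averaged excitatory and
#' inhibitory synaptic currents over the stimulus window, reported as
#' magnitudes.
#'
#' @param I_synE,I_synI network-averaged synaptic current series (uA/cm2).
#' @param times time grid (ms).
#' @param window integration window length (ms), starting at 0.
#' @return numeric vector `c(Q_synE, Q_synI)` (uA ms/cm2, magnitudes).
#' @export
synaptic_charge <- function(I_synE, I_synI, times, window = 50) {
  stopifnot(length(I_synE) == length(times), length(I_synI) == length(times))
  sel <- times <= window
  trapz <- function(x, y) {
    if (sum(sel) < 2L) return(0)
    sum(diff(x[sel]) * (utils::head(y[sel], -1) + utils::tail(y[sel], -1)) / 2)
  }
  c(Q_synE = abs(trapz(times, I_synE)), Q_synI = abs(trapz(times, I_synI)))
}
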