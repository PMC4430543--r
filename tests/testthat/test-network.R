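test_that("architecture generation is reproducible and parameter-faithful", {
  n1 <- generate_network(seed = 7)
  n2 <- generate_network(seed = 7)
  expect_identical(n1$S_ex, n2$S_ex)
  expect_identical(n1$S_in, n2$S_in)
  # mean indegree over 12 seeds near the drawn mean
  mi <- vapply(1:12, function(sd) mean(generate_network(seed = sd)$indegree), numeric(1))
  expect_gt(mean(mi), 24); expect_lt(mean(mi), 26)
  # no excitatory synapses when p_exc = 0
  n0 <- generate_network(p_exc = 0, seed = 1)
  expect_true(all(lengths(n0$S_ex) == 0L))
  expect_error(generate_network(N = 10, mu = 25), "exceed N")
})

test_that("synaptic gate is logistic with the documented landmarks", {
  sp <- synapse_params()
  expect_equal(synaptic_gate(sp$V_syn, sp), 0.5)
  expect_lt(synaptic_gate(-100, sp), 1e-10)
  expect_gt(synaptic_gate(200, sp), 1 - 1e-10)
  v <- seq(-20, 60, by = 1)
  expect_true(all(diff(synaptic_gate(v, sp)) > 0))
})

test_that("an unstimulated or disconnected network stays silent", {
  net <- generate_network(N = 20, mu = 5, sigma = 1, seed = 2)
  s <- simulate_network(net, p = patch_params(alpha = 1),
                        cfg = solver_config(dt = 1e-3, t_end = 30),
                        stim_amplitude = 0)
  expect_identical(nrow(s$raster), 0L)
  expect_lt(max(abs(s$pEEG)), 0.5)
  expect_identical(s$activity_duration, 0)
  # the sigmoid gate never vanishes exactly at rest; the residual charge is tiny
  expect_lt(unname(s$Q_synE), 0.05)
})

test_that("with no coupling the pEEG averages identical uncoupled neurons", {
  net <- generate_network(N = 10, mu = 5, sigma = 0, seed = 3)
  s <- simulate_network(net, sp = synapse_params(g_syn = 0), p = patch_params(alpha = 1),
                        cfg = solver_config(dt = 1e-3, t_end = 40),
                        stim_amplitude = 20, stim_duration = 40, n_stim = 10L)
  # all 10 neurons stimulated identically and uncoupled: Lambda(t) = v_1(t)
  tr <- simulate_patch(patch_params(alpha = 1),
                       stimulus("step", amplitude = 20, onset = 0, duration = 40),
                       solver_config(dt = 1e-3, t_end = 40))
  expect_lt(max(abs(s$pEEG - tr$v)), 1e-6)
})

test_that("network runs are fully determined by the two seeds", {
  net <- generate_network(seed = 11)
  a <- simulate_network(net, p = patch_params(alpha = 1),
                        cfg = solver_config(dt = 1e-3, t_end = 80), stim_seed = 5)
  b <- simulate_network(net, p = patch_params(alpha = 1),
                        cfg = solver_config(dt = 1e-3, t_end = 80), stim_seed = 5)
  expect_identical(a$raster, b$raster)
  expect_identical(a$pEEG, b$pEEG)
  d <- simulate_network(net, p = patch_params(alpha = 1),
                        cfg = solver_config(dt = 1e-3, t_end = 80), stim_seed = 6)
  expect_false(identical(a$stim_neurons, d$stim_neurons))
})

test_that("sliding-window firing rate matches simple counting", {
  expect_true(all(firing_rate(data.frame(neuron = integer(), time = numeric()),
                              N = 50, t_end = 200)$rate == 0))
  # one spike per neuron inside one window
  r <- firing_rate(data.frame(neuron = 1:50, time = rep(25, 50)), N = 50, t_end = 100)
  expect_identical(max(r$rate), 1)
  expect_identical(min(r$rate), 0)
})

test_that("firing rate recovers a Poisson spike rate", {
  set.seed(99)
  N <- 50; t_end <- 1000; rate_hz <- 20
  n_spk <- rpois(1, N * rate_hz * t_end / 1000)
  times <- runif(n_spk, 0, t_end)
  r <- firing_rate(data.frame(neuron = sample(1:N, n_spk, TRUE), time = times),
                   N = N, t_end = t_end)
  # expected spikes/neuron/50-ms window = 1; SE of the mean over windows
  expected <- rate_hz * 0.05
  se <- sqrt(expected / N) / sqrt(nrow(r))
  expect_lt(abs(mean(r$rate) - expected), 3 * se + 0.05)
})

test_that("synaptic charge integrates the stimulus window correctly", {
  tt <- seq(0, 100, by = 0.1)
  zero <- synaptic_charge(numeric(length(tt)), numeric(length(tt)), tt)
  expect_identical(unname(zero), c(0, 0))
  const <- synaptic_charge(rep(-2, length(tt)), rep(0.5, length(tt)), tt, window = 50)
  expect_equal(unname(const), c(100, 25), tolerance = 1e-10)
  # trapezoid quadrature reaches O(dt^2) accuracy on a smooth signal, while
  # a left-rectangle rule only gets O(dt)
  f <- sin(tt / 8)
  trap <- unname(synaptic_charge(f, f, tt, window = 50)[1])
  exact <- abs(8 * (1 - cos(50 / 8)))
  rect <- abs(sum(f[tt < 50] * 0.1))
  expect_lt(abs(trap - exact), 1e-5)
  expect_gt(abs(rect - exact), 1e-4)
})

test_that("a stimulated network shows recurrent activity beyond the stimulated set", {
  net <- generate_network(seed = 1)
  s <- simulate_network(net, p = patch_params(alpha = 1),
                        cfg = solver_config(dt = 1e-3, t_end = 100, record_stride = 10L),
                        stim_seed = 1)
  expect_gt(nrow(s$raster), 20)
  expect_gt(length(unique(s$raster$neuron)), 13)   # spread beyond stimulated neurons
  expect_gt(s$Q_synE, 0); expect_gt(s$Q_synI, 0)
  expect_true(is.data.frame(s$firing_rate))
})
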