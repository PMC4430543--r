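test_that("gating rates handle the removable singularities exactly", {
  r25 <- gating_rates(25)
  expect_equal(r25$alpha_m, 1.0, tolerance = 1e-9)
  r10 <- gating_rates(10)
  expect_equal(r10$alpha_n, 0.1, tolerance = 1e-9)
  # continuity through the series window
  v <- c(24.999999, 25, 25.000001)
  am <- gating_rates(v)$alpha_m
  expect_lt(max(abs(am - 1)), 1e-6)
})

test_that("resting-state gate steady values match a high-precision evaluation", {
  r <- gating_rates(0)
  expect_equal(r$alpha_m / (r$alpha_m + r$beta_m), 0.0529324852572, tolerance = 1e-10)
  expect_equal(r$alpha_h / (r$alpha_h + r$beta_h), 0.596120753508, tolerance = 1e-10)
  expect_equal(r$alpha_n / (r$alpha_n + r$beta_n), 0.317676914061, tolerance = 1e-10)
})

test_that("rest is a fixed point for any order", {
  for (a in c(1, 0.6)) {
    tr <- simulate_patch(patch_params(alpha = a), stimulus("none"),
                         solver_config(dt = if (a == 1) 1e-3 else 5e-4, t_end = 50))
    expect_lt(max(abs(tr$v)), 0.5)
  }
})

test_that("classical brief-pulse response is a single spike with after-hyperpolarization", {
  p <- patch_params(alpha = 1)
  thr <- find_threshold(p)
  tr <- simulate_patch(p, stimulus("pulse", amplitude = 1.5 * thr, onset = 1, duration = 0.1),
                       solver_config(dt = 1e-3, t_end = 25))
  sp <- detect_spikes(tr)
  expect_identical(length(sp$peak_times), 1L)
  expect_gt(max(tr$v), 85); expect_lt(max(tr$v), 115)
  expect_lt(min(tr$v), 0)                          # hyperpolarizing overshoot
  expect_lt(abs(tr$v[length(tr$v)]), 1)            # back at rest
})

test_that("alpha = 1 simulation equals the independent Euler reference", {
  tr <- simulate_patch(patch_params(alpha = 1),
                       stimulus("step", amplitude = 20, onset = 0, duration = Inf),
                       solver_config(dt = 1e-3, t_end = 50))
  ref <- ref_hh_euler(function(t) 20, 1e-3, 50)
  expect_lt(max(abs(tr$v - ref$v)), 0.1)
})

test_that("decreasing order gives an earlier spike peak, larger peak I_Na, larger h_peak", {
  res <- lapply(c(1, 0.6), function(a) {
    p <- patch_params(alpha = a)
    thr <- find_threshold(p, cfg = solver_config(dt = 5e-4, t_end = 20))
    tr <- simulate_patch(p, stimulus("pulse", amplitude = 1.5 * thr, onset = 1, duration = 0.1),
                         solver_config(dt = 5e-4, t_end = 20))
    i_pk <- which.max(abs(tr$I_Na))
    list(t_peak = detect_spikes(tr)$peak_times[1],
         peak_INa = max(abs(tr$I_Na)), h_peak = tr$h[i_pk],
         peak_vmem = max(abs(tr$v_mem)))
  })
  expect_lt(res[[2]]$t_peak, res[[1]]$t_peak)
  expect_gt(res[[2]]$peak_INa, res[[1]]$peak_INa)
  expect_gt(res[[2]]$h_peak, res[[1]]$h_peak)
  expect_gt(res[[2]]$peak_vmem, res[[1]]$peak_vmem)  # memory trace grows as alpha drops
})

test_that("gates stay in [0,1] under extreme stimuli", {
  # hyperpolarizing currents are capped so the passive equilibrium I/g_L
  # stays inside the instability guard (|v| < 1000 mV)
  for (amp in c(-250, 500)) {
    tr <- simulate_patch(patch_params(alpha = 0.8),
                         stimulus("step", amplitude = amp, onset = 0, duration = Inf),
                         solver_config(dt = 1e-3, t_end = 20))
    expect_true(all(tr$m >= 0 & tr$m <= 1))
    expect_true(all(tr$h >= 0 & tr$h <= 1))
    expect_true(all(tr$n >= 0 & tr$n <= 1))
  }
})

test_that("recorded memory trace equals the definition applied to the voltage history", {
  tr <- simulate_patch(patch_params(alpha = 0.7),
                       stimulus("pulse", amplitude = 100, onset = 0.5, duration = 0.1),
                       solver_config(dt = 1e-3, t_end = 5, memory = "full"))
  w <- gl_weights(0.7, length(tr$v))
  expect_equal(tr$v_mem, memory_trace(tr$v, w), tolerance = 1e-9)
  expect_identical(tr$v_mem[1:2], c(0, 0))
})

test_that("instability is reported with the failing step", {
  expect_error(simulate_patch(patch_params(alpha = 0.4),
                              stimulus("step", amplitude = 200, onset = 0, duration = Inf),
                              solver_config(dt = 0.5, t_end = 50)),
               "instability.*smaller dt")
})

test_that("simulate() generic dispatches on patch parameters", {
  tr <- simulate(patch_params(alpha = 1), stim = stimulus("none"),
                 cfg = solver_config(dt = 1e-2, t_end = 5))
  expect_s3_class(tr, "fhh_trajectory")
})
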