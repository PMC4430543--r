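test_that("a spatially uniform stimulus reproduces the patch at every node", {
  cfg <- solver_config(dt = 1e-3, t_end = 15)
  s <- stimulus("step", amplitude = 20, onset = 0, duration = Inf)
  ctr <- simulate_cable(patch_params(alpha = 0.8), cable_grid(), s, cfg,
                        uniform_stimulus = TRUE)
  ptr <- simulate_patch(patch_params(alpha = 0.8), s, cfg)
  for (node in c(1, 11, 21))
    expect_lt(max(abs(ctr$v[, node] - ptr$v)), 1e-8)
})

test_that("the sealed-end diffusion operator conserves total charge", {
  # no conductances, no stimulus after a brief kick: sum(v) must stay fixed
  p0 <- patch_params(alpha = 1, conductance_scale = c(0, 0, 0), g_L = 0)
  tr <- simulate_cable(p0, cable_grid(),
                       stimulus("pulse", amplitude = 100, onset = 0, duration = 0.5),
                       solver_config(dt = 1e-3, t_end = 10))
  sums <- rowSums(tr$v)
  after <- sums[tr$times > 0.6]
  expect_lt(diff(range(after)) / mean(after), 1e-10)
})

test_that("velocity of a synthetic traveling pulse is recovered", {
  x <- seq(0, 1, by = 0.05); tt <- seq(0, 10, by = 0.005)
  c_true <- 1  # cm/ms
  v <- outer(tt, x, function(t, xx) 100 * exp(-((t - 2 - xx / c_true)^2) / 0.05))
  traj <- structure(list(times = tt, v = v, x = x, alpha = 1, dt = 0.005,
                         memory = "full"),
                    class = c("fhh_cable_trajectory", "fhh_trajectory"))
  vel <- measure_velocity(traj)
  expect_equal(vel$velocity[1], c_true, tolerance = 0.01)
})

test_that("a brief pulse launches a spike that traverses the full cable", {
  tr <- simulate_cable(patch_params(alpha = 1), cable_grid(g_axial = 7.06),
                       stimulus("pulse", amplitude = 500, onset = 0.5, duration = 0.1),
                       solver_config(dt = 1e-3, t_end = 15))
  sp_end <- detect_spikes(tr$v[, 21], tr$times)
  expect_identical(length(sp_end$peak_times), 1L)
  expect_gt(max(tr$v[, 21]), 85)
})

test_that("propagation is faster at smaller order and velocity is monotone in alpha", {
  run <- function(a, dt) {
    tr <- simulate_cable(patch_params(alpha = a), cable_grid(g_axial = 7.06),
                         stimulus("pulse", amplitude = 500, onset = 0.5, duration = 0.1),
                         solver_config(dt = dt, t_end = 12,
                                       record_stride = max(1L, as.integer(1e-3 / dt))))
    list(vel = measure_velocity(tr)$velocity[1],
         arrival = detect_spikes(tr$v[, 21], tr$times)$peak_times[1])
  }
  r1 <- run(1, 1e-3); r8 <- run(0.8, 1e-3); r6 <- run(0.6, 5e-4)
  expect_lt(r6$arrival, r1$arrival)
  expect_true(r6$vel > r8$vel && r8$vel > r1$vel)
})

test_that("halving the spatial step changes the first-order velocity by under 5%", {
  run_dx <- function(dx) {
    tr <- simulate_cable(patch_params(alpha = 1), cable_grid(dx = dx, g_axial = 7.06),
                         stimulus("pulse", amplitude = 500, onset = 0.5, duration = 0.1),
                         solver_config(dt = 1e-3, t_end = 15))
    measure_velocity(tr)$velocity[1]
  }
  expect_lt(abs(run_dx(0.025) / run_dx(0.05) - 1), 0.05)
})

test_that("constant stimulus: first spike equals the brief-pulse velocity, series non-increasing", {
  vs <- constant_stimulus_velocity_series(patch_params(alpha = 1),
                                          cable_grid(g_axial = 7.06), I_app = 20,
                                          cfg = solver_config(dt = 1e-3, t_end = 60))
  trp <- simulate_cable(patch_params(alpha = 1), cable_grid(g_axial = 7.06),
                        stimulus("pulse", amplitude = 500, onset = 0.5, duration = 0.1),
                        solver_config(dt = 1e-3, t_end = 15))
  v_pulse <- measure_velocity(trp)$velocity[1]
  expect_equal(vs$velocity[1], v_pulse, tolerance = 0.02)
  expect_true(all(diff(vs$velocity) < 0.02 * vs$velocity[1]))  # within measurement noise
  expect_identical(vs$pct_change_from_final[length(vs$pct_change_from_final)], 0)
})

test_that("grid construction validates its arguments and warns near instability", {
  expect_error(cable_grid(dx = 0.03), "integer")
  expect_identical(cable_grid()$n_nodes, 21L)
  expect_warning(simulate_cable(patch_params(alpha = 1), cable_grid(g_axial = 7.06),
                                stimulus("none"),
                                solver_config(dt = 0.5, t_end = 2)),
                 "stability")
})

test_that("velocity measurement demands spikes at the proximal probe", {
  tr <- simulate_cable(patch_params(alpha = 1), cable_grid(),
                       stimulus("none"), solver_config(dt = 1e-3, t_end = 5))
  expect_error(measure_velocity(tr), "no spikes")
})
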