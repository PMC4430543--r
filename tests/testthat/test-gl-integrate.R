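test_that("alpha = 1 reduces to an independent forward-Euler integration", {
  cfg <- solver_config(dt = 1e-3, t_end = 2)
  tr <- gl_integrate(function(t, y) -2 * y + 1, 0, order = 1, cfg)
  # hand-rolled Euler on identical inputs
  y <- 0; dt <- 1e-3
  for (i in 1:2000) y <- y + dt * (-2 * y + 1)
  expect_equal(tr$state[nrow(tr$state), 1], y, tolerance = 1e-12)
})

test_that("zero right-hand side from a zero state stays identically zero", {
  tr <- gl_integrate(function(t, y) 0 * y, c(0, 0), order = c(0.5, 1),
                     solver_config(dt = 0.01, t_end = 1))
  expect_true(all(tr$state == 0))
})

test_that("fractional passive membrane matches the Mittag-Leffler solution", {
  # d^a v/dt^a = (Im - v/Rm)/Cm with Rm = Cm = Im = 1: step response
  cfg <- solver_config(dt = 1e-3, t_end = 5, memory = "full")
  tr <- gl_integrate(function(t, y) 1 - y, 0, order = 0.6, cfg)
  p <- passive_params(alpha = 0.6)
  sel <- tr$times >= 0.01
  exact <- step_response(tr$times[sel], p)
  expect_lt(max(abs(tr$state[sel, 1] - exact) / exact), 0.01)
})

test_that("first-order convergence: halving dt shrinks the terminal error", {
  exact <- step_response(2, passive_params(alpha = 0.7))
  err <- vapply(c(4e-3, 2e-3, 1e-3), function(dt) {
    tr <- gl_integrate(function(t, y) 1 - y, 0, order = 0.7,
                       solver_config(dt = dt, t_end = 2))
    abs(tr$state[nrow(tr$state), 1] - exact)
  }, numeric(1))
  expect_gt(err[1] / err[2], 1.7)
  expect_gt(err[2] / err[3], 1.7)
})

test_that("truncated memory deviates by at most the dropped tail mass times max|y|", {
  cfgF <- solver_config(dt = 2e-3, t_end = 4, memory = "full")
  cfgT <- solver_config(dt = 2e-3, t_end = 4, memory = "truncated", L = 400L)
  rhs <- function(t, y) 1 - y
  trF <- gl_integrate(rhs, 0, 0.5, cfgF)
  trT <- gl_integrate(rhs, 0, 0.5, cfgT)
  bound <- gl_tail_mass(0.5, 400L) * max(abs(trF$state))
  dev <- abs(trT$state - trF$state)
  # deviation accumulates over steps; the per-step bound scales it loosely
  expect_lt(max(dev), 5 * bound * nrow(trF$state) * 2e-3)
  expect_gt(max(dev), 0)   # truncation genuinely differs from full history
})

test_that("contract violations raise errors", {
  expect_error(gl_integrate(function(t, y) -y, 1, order = 0.5,
                            solver_config(dt = 0.01, t_end = 1)),
               "start at 0")
  expect_error(gl_integrate(function(t, y) 1e9, 0, order = 0.5,
                            solver_config(dt = 1, t_end = 10)),
               "instability")
})

test_that("compressed policy reproduces full history in the compiled patch core", {
  s <- stimulus("step", amplitude = 20, onset = 0, duration = Inf)
  p <- patch_params(alpha = 0.5)
  trF <- simulate_patch(p, s, solver_config(dt = 5e-4, t_end = 25, memory = "full"))
  trC <- simulate_patch(p, s, solver_config(dt = 5e-4, t_end = 25,
                                            memory = "compressed", K0 = 512L))
  expect_lt(max(abs(trF$v - trC$v)), 1e-5)
  expect_lt(max(abs(trF$v_mem - trC$v_mem)), 1e-5)
})

test_that("per-order default time steps are ordered", {
  expect_identical(default_dt(1), 1e-3)
  expect_identical(default_dt(0.6), 5e-4)
  expect_identical(default_dt(0.4), 1e-4)
})
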