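test_that("step response starts at zero and recovers the exponential at alpha = 1", {
  p1 <- passive_params(alpha = 1)
  expect_equal(step_response(0, p1), 0)
  tt <- c(0.1, 0.5, 1, 3)
  expect_equal(step_response(tt, p1, Im = 2), 2 * (1 - exp(-tt)), tolerance = 1e-10)
  expect_error(step_response(-1, p1), ">= 0")
})

test_that("fractional membrane charges faster early, slower late", {
  p6 <- passive_params(alpha = 0.6); p1 <- passive_params(alpha = 1)
  expect_gt(step_response(0.05, p6), step_response(0.05, p1))
  expect_lt(step_response(10, p6), step_response(10, p1))
  # monotone nondecreasing, saturating at Rm * Im
  tt <- 10^seq(-2, 2, by = 0.25)
  v <- step_response(tt, p6)
  expect_true(all(diff(v) > 0))
  expect_lt(max(v), 1)
  expect_gt(v[length(v)], 0.9)
})

test_that("strength-duration: classical limit, rheobase asymptote, power-law slope", {
  d <- c(0.05, 0.3, 2)
  expect_equal(strength_duration(d, 1), 1 / (1 - exp(-d)), tolerance = 1e-10)
  expect_lt(abs(strength_duration(100, 0.8) - 1), 0.01)
  # log-log slope approx -alpha for short stimuli
  for (a in c(0.5, 0.8)) {
    dd <- 10^seq(-4, -2, by = 0.25)
    sl <- stats::coef(stats::lm(log(strength_duration(dd, a)) ~ log(dd)))[2]
    expect_lt(abs(sl + a), 0.05)
  }
  # decreasing in duration
  dd <- 10^seq(-3, 2, by = 0.2)
  expect_true(all(diff(strength_duration(dd, 0.6)) < 0))
  expect_error(strength_duration(0, 0.6), "> 0")
})

test_that("strength-duration and step response are mutually consistent", {
  # driving the membrane for duration d at the threshold current reaches
  # exactly the rheobase-defined threshold voltage Rm * I_rheo
  for (a in c(0.5, 0.9)) {
    p <- passive_params(alpha = a)
    for (d in c(0.05, 0.5, 3))
      expect_equal(step_response(d, p, Im = strength_duration(d, a)), 1,
                   tolerance = 1e-9)
  }
})

test_that("impedance magnitude and phase behave as a constant-phase element", {
  for (a in c(0.4, 0.5, 0.7, 1)) {
    p <- passive_params(alpha = a)
    expect_equal(Mod(impedance(0, p)), 1)
    # the plateau is approached as (omega*tau)^alpha, slowly for small alpha
    expect_lt(abs(Mod(impedance(1e-6, p)) - 1), 0.01)
    expect_equal(impedance_phase(1e4, p), -90 * a, tolerance = 1)
    w <- 10^seq(-1, 3, by = 0.2)
    expect_true(all(diff(Mod(impedance(w, p))) < 0))        # low-pass
  }
})

test_that("analytic results are continuous in alpha near 1", {
  p999 <- passive_params(alpha = 0.999); p1 <- passive_params(alpha = 1)
  tt <- c(0.1, 1, 5)
  expect_equal(step_response(tt, p999), step_response(tt, p1), tolerance = 0.01)
  expect_equal(strength_duration(c(0.1, 1), 0.999), strength_duration(c(0.1, 1), 1),
               tolerance = 0.01)
})
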