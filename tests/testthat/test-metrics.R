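test_that("a flat trace yields an empty spike train", {
  sp <- detect_spikes(rep(0.3, 500), times = seq(0, 50, length.out = 500))
  expect_identical(length(sp$peak_times), 0L)
  expect_identical(length(sp$inst_freq), 0L)
})

test_that("synthetic bump peaks are recovered to sub-sample accuracy", {
  tt <- seq(0, 40, by = 0.02)
  true_peaks <- c(8.37, 23.91)
  v <- 100 * exp(-(tt - true_peaks[1])^2 / 0.5) + 90 * exp(-(tt - true_peaks[2])^2 / 0.8)
  sp <- detect_spikes(v, tt)
  expect_identical(length(sp$peak_times), 2L)
  expect_equal(sp$peak_times, true_peaks, tolerance = 0.02)
  expect_equal(sp$isi, diff(true_peaks), tolerance = 0.04)
})

test_that("sub-threshold noise does not create spurious spikes", {
  set.seed(42)
  tt <- seq(0, 40, by = 0.02)
  v <- 100 * exp(-(tt - 10)^2 / 0.5) + rnorm(length(tt))
  sp <- detect_spikes(v, tt)
  expect_identical(length(sp$peak_times), 1L)
  expect_equal(sp$peak_times, 10, tolerance = 0.05)
})

test_that("classical repetitive firing at I_app = 20 produces at least 5 spikes", {
  ref <- ref_hh_euler(function(t) 20, 1e-3, 100)
  sp_ref <- detect_spikes(ref$v, ref$times)
  expect_gte(length(sp_ref$peak_times), 5L)
  tr <- simulate_patch(patch_params(alpha = 1),
                       stimulus("step", amplitude = 20, onset = 0, duration = Inf),
                       solver_config(dt = 1e-3, t_end = 100))
  expect_identical(length(detect_spikes(tr)$peak_times), length(sp_ref$peak_times))
})

test_that("threshold bisection brackets the spike boundary", {
  p <- patch_params(alpha = 1)
  thr <- find_threshold(p)
  expect_gt(thr, 0); expect_true(is.finite(thr))
  cfg <- solver_config(dt = 1e-3, t_end = 20)
  n_below <- length(detect_spikes(simulate_patch(p,
    stimulus("pulse", amplitude = 0.99 * thr - 0.5, onset = 1, duration = 0.1), cfg))$peak_times)
  n_above <- length(detect_spikes(simulate_patch(p,
    stimulus("pulse", amplitude = 1.01 * thr, onset = 1, duration = 0.1), cfg))$peak_times)
  expect_identical(n_below, 0L)
  expect_identical(n_above, 1L)
})

test_that("threshold varies continuously with the order", {
  thr1 <- find_threshold(patch_params(alpha = 1))
  thr95 <- find_threshold(patch_params(alpha = 0.95),
                          cfg = solver_config(dt = 1e-3, t_end = 20))
  expect_lt(abs(thr95 - thr1) / thr1, 0.3)
})

test_that("refractory interval exceeds the time to peak", {
  r <- refractory_interval(patch_params(alpha = 1))
  expect_gt(r$difference, 0)
  expect_equal(r$min_interstimulus - r$time_to_peak, r$difference)
})

test_that("asymptotic statistics flag non-spiking windows", {
  tr <- simulate_patch(patch_params(alpha = 1), stimulus("none"),
                       solver_config(dt = 1e-3, t_end = 100))
  s <- asymptotic_spike_stats(tr)
  expect_false(s$spiking)
  expect_identical(s$freq, 0)
})

test_that("metrics are invariant to recording stride", {
  s <- stimulus("step", amplitude = 50, onset = 0, duration = Inf)
  f <- vapply(c(1L, 2L), function(st) {
    tr <- simulate_patch(patch_params(alpha = 1), s,
                         solver_config(dt = 5e-4, t_end = 100, record_stride = st))
    asymptotic_spike_stats(tr)$freq
  }, numeric(1))
  expect_lt(abs(f[2] / f[1] - 1), 0.01)
})

test_that("spiking range at alpha = 1 brackets the classical firing band", {
  sr <- spiking_range(patch_params(alpha = 1), I_grid = seq(5, 200, by = 15))
  expect_true(sr$found)
  expect_lt(sr$I1, 20); expect_gt(sr$I1, 2)
  expect_gt(sr$I2, 100); expect_lt(sr$I2, 200)
  # independent reference classification at three currents
  classify <- function(I) {
    ref <- ref_hh_euler(function(t) I, 1e-3, 100)
    sp <- detect_spikes(ref$v, ref$times)
    sum(sp$peak_times >= 70) >= 2
  }
  expect_false(classify(2))
  expect_true(classify(20))
  expect_false(classify(190))
})
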