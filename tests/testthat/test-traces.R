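test_that("trace constructor validates input", {
  expect_error(trace(1), "at least 2")
  expect_error(trace(c(1, NA), 10000), "finite")
  expect_error(trace(c(1, 2), 0), "> 0")
  x <- trace(c(1, 2, 3), 1000, units = "nA", start_time_s = 0.5)
  expect_s3_class(x, "trace")
  expect_equal(trace_times(x), c(0.5, 0.501, 0.502))
})

test_that("average_sweeps is the pointwise mean", {
  t1 <- trace(c(1, 2, 3, 4), 100)
  t2 <- trace(c(3, 2, 1, 0), 100)
  avg <- average_sweeps(list(t1, t2))
  expect_equal(avg$values, c(2, 2, 2, 2))
  expect_error(average_sweeps(list(t1, trace(c(1, 2), 100))), "lengths")
  expect_error(average_sweeps(list(t1, trace(c(1, 2, 3, 4), 200))), "rates")
})

test_that("artefact blanking interpolates linearly over the blank window", {
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)
  v <- 2 * t            # linear signal: interpolation restores it exactly
  v[501:504] <- 99      # artefact at 0.500-0.503 s
  x <- trace(v, fs)
  stims <- stimulus_train(0.5)
  out <- remove_stimulus_artefacts(x, stims, blank_window_ms = 3)
  expect_equal(out$values, 2 * t)
  expect_error(remove_stimulus_artefacts(x, stimulus_train(0.9999)),
               "outside|beyond")
})

test_that("peak_amplitude subtracts the baseline window mean", {
  fs <- 1000
  v <- rep(0.5, 1001)
  v[300:310] <- 2.5
  x <- trace(v, fs)
  expect_equal(peak_amplitude(x, c(0.2, 0.5), c(0, 0.1)), 2.0)
  expect_error(peak_amplitude(x, c(0.05, 0.5), c(0, 0.1)), "precede")
})

test_that("rise_time_20_80 is exact on a linear ramp", {
  x <- ramp_trace(onset_s = 0.1, ramp_s = 0.02, peak = 3)
  rt <- rise_time_20_80(x, 0.1, c(0, 0.09))
  expect_equal(rt, 0.6 * 0.02 * 1000, tolerance = 1e-9)
})

test_that("area_under_curve is exact on a rectangle", {
  fs <- 1000
  v <- rep(0, 1001)
  v[201:401] <- 2.5     # rectangle on [0.2, 0.4] s
  x <- trace(v, fs)
  expect_equal(area_under_curve(x, 0.2, 0.2), 2.5 * 0.2)
})

test_that("train_amplitudes uses the local pre-stimulus value", {
  fs <- 1000
  v <- rep(0, 1001)
  v[102:1001] <- 1      # first response to 1 (starts after the onset sample)
  v[302:1001] <- 1.6    # second response summates to 1.6
  x <- trace(v, fs)
  stims <- stimulus_train(c(0.1, 0.3))
  res <- train_amplitudes(x, stims, reference_first_amplitude = 1)
  expect_equal(res$amplitudes_um, c(1, 0.6))
  expect_equal(res$normalized, c(1, 0.6))
})

test_that("dat_block_comparison on identical traces gives fold 1, difference 0", {
  g <- generate_trace(trace_spec(duration_s = 1.0, stimulus_times_s = 0,
                                 amplitude_um = 1.5, seed = 7L))
  res <- dat_block_comparison(g$concentration, g$concentration,
                              window = c(0, 0.9))
  expect_identical(res$subtracted_area, 0)
  expect_identical(res$fold_increase, 1)
})

test_that("dat_block_comparison returns NA fold for non-positive baseline", {
  z <- trace(rep(0, 100), 100)
  res <- dat_block_comparison(z, z, window = c(0, 0.5))
  expect_true(is.na(res$fold_increase))
  expect_identical(res$subtracted_area, 0)
})

test_that("kcl_response integrates a rectangle pulse over the standard window", {
  fs <- 100
  dur <- 230
  t <- seq(0, dur, by = 1 / fs)
  v <- rep(0.2, length(t))                 # baseline 0.2
  v[t >= 20 & t <= 30] <- 1.2              # 1 uM above baseline for 10 s
  x <- trace(v, fs)
  res <- kcl_response(x, puff_start_s = 20, puff_duration_s = 10, post_s = 200,
                      baseline_window = c(5, 15))
  expect_equal(res$peak_um, 1.0)
  expect_equal(res$auc_um_s, 10, tolerance = 1e-2)
})

test_that("normalize_microdialysis normalizes to the reference window", {
  tm <- seq(0, 180, by = 4)
  conc <- rep(2, length(tm))
  conc[tm > 120] <- 4
  res <- normalize_microdialysis(tm, conc)
  expect_equal(res$reference_mean, 2)
  expect_equal(res$normalized[tm <= 120], rep(1, sum(tm <= 120)))
  expect_equal(res$log_normalized, log(res$normalized))
  # external reference mean (control-group normalization)
  res2 <- normalize_microdialysis(tm, conc, reference_mean = 4)
  expect_equal(res2$normalized[tm > 120], rep(1, sum(tm > 120)))
  expect_error(normalize_microdialysis(tm, conc - 2), "non-positive|> 0")
})

test_that("lowpass_trace attenuates high-frequency noise", {
  set.seed(42)
  x <- trace(rnorm(10000), 10000)
  y <- lowpass_trace(x, 400)
  expect_lt(var(y$values), 0.2 * var(x$values))
  expect_error(lowpass_trace(x, 10000), "Nyquist")
})
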