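test_that("generate_trace is deterministic for a fixed seed", {
  spec <- trace_spec(duration_s = 0.5, stimulus_times_s = 0.05,
                     noise_sd_um = 0.05, artefact_amplitude_na = 3, seed = 11L)
  g1 <- generate_trace(spec)
  g2 <- generate_trace(spec)
  expect_identical(g1$current$values, g2$current$values)
  expect_identical(g1$truth, g2$truth)
})

test_that("truth peak equals the requested amplitude", {
  g <- generate_trace(trace_spec(duration_s = 1.5, stimulus_times_s = 0.1,
                                 amplitude_um = 2.4, tau_rise_ms = 1,
                                 tau_decay_ms = 60, seed = 3L))
  expect_equal(g$truth$true_peak_um[1], 2.4, tolerance = 1e-5)
})

test_that("truth rise time matches the closed-form oracle", {
  for (taus in list(c(1, 60), c(0.5, 30), c(2, 40))) {
    g <- generate_trace(trace_spec(duration_s = 1.0, stimulus_times_s = 0.05,
                                   tau_rise_ms = taus[1], tau_decay_ms = taus[2],
                                   seed = 5L))
    expect_equal(g$truth$true_rise_time_20_80_ms[1],
                 oracle_rise_ms(taus[1], taus[2]), tolerance = 1e-3)
  }
})

test_that("truth AUC matches the analytic finite-window integral", {
  g <- generate_trace(trace_spec(duration_s = 4.0, stimulus_times_s = 0.1,
                                 amplitude_um = 2, tau_rise_ms = 1,
                                 tau_decay_ms = 60, seed = 9L))
  expect_equal(g$truth$true_auc_um_s,
               oracle_auc_window(2, 1, 60, 2.935), tolerance = 1e-6)
})

test_that("stimulus artefact lands on the onset sample of the current trace", {
  spec <- trace_spec(duration_s = 0.2, stimulus_times_s = 0.05,
                     amplitude_um = 0, artefact_amplitude_na = 10, seed = 2L)
  g <- generate_trace(spec)
  i_on <- 0.05 * spec$sampling_rate_hz + 1
  expect_equal(g$current$values[i_on], 10)
  expect_true(all(g$current$values[-i_on] == 0))
})

test_that("current maps concentration through the stated calibration", {
  spec <- trace_spec(duration_s = 0.5, stimulus_times_s = 0.05,
                     calibration_slope_na_per_um = 3,
                     calibration_intercept_na = 0.5, seed = 4L)
  g <- generate_trace(spec)
  expect_equal(g$current$values, 3 * g$concentration$values + 0.5)
})

test_that("clearance_scale stretches the decay tail", {
  base <- generate_trace(trace_spec(duration_s = 2, stimulus_times_s = 0,
                                    clearance_scale = 1, seed = 6L))
  slow <- generate_trace(trace_spec(duration_s = 2, stimulus_times_s = 0,
                                    clearance_scale = 4, seed = 6L))
  a0 <- area_under_curve(base$concentration, 0, 1.9)
  a1 <- area_under_curve(slow$concentration, 0, 1.9)
  expect_gt(a1, a0)
})

test_that("trace_spec rejects inconsistent kinetics", {
  expect_error(trace_spec(tau_rise_ms = 60, tau_decay_ms = 60), "tau_rise")
  expect_error(trace_spec(stimulus_times_s = 5, duration_s = 2), "within")
  expect_error(trace_spec(noise_sd_um = -1), ">= 0")
})

test_that("dopamine_transient peaks at the requested amplitude", {
  t <- seq(0, 1, by = 1e-5)
  v <- dopamine_transient(t, 3, 1, 60)
  expect_equal(max(v), 3, tolerance = 1e-6)
  expect_equal(dopamine_transient(-0.01, 3, 1, 60), 0)
})

test_that("dopamine_transient_auc equals the numeric integral", {
  num <- integrate(dopamine_transient, 0, Inf, amplitude_um = 2,
                   tau_rise_ms = 1.5, tau_decay_ms = 45)$value
  expect_equal(dopamine_transient_auc(2, 1.5, 45), num, tolerance = 1e-6)
})
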