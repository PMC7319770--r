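test_that("fit_calibration recovers a known line", {
  conc <- c(0, 1, 5, 10, 20)
  cal <- fit_calibration(conc, 1.5 * conc + 0.2)
  expect_equal(cal$slope_na_per_um, 1.5)
  expect_equal(cal$intercept_na, 0.2)
  expect_equal(cal$r_squared, 1)
  expect_true(cal$usable)
})

test_that("nonlinear electrodes are flagged unusable", {
  conc <- c(0, 1, 5, 10, 20)
  cal <- fit_calibration(conc, sqrt(conc))
  expect_false(cal$usable)
  expect_lt(cal$r_squared, 0.98)
})

test_that("negative-slope electrodes are unusable", {
  cal <- fit_calibration(c(0, 1, 5, 10, 20), -2 * c(0, 1, 5, 10, 20))
  expect_false(cal$usable)
})

test_that("calibration needs at least two distinct concentrations", {
  expect_error(fit_calibration(c(5, 5, 5), c(1, 2, 3)), "distinct")
})

test_that("current/concentration conversion round-trips", {
  conc <- c(0, 1, 5, 10, 20)
  cal <- fit_calibration(conc, 2 * conc + 0.1)
  x_um <- trace(c(0.5, 1.2, 0.8, 2.0), 10000, units = "uM")
  x_na <- concentration_to_current(x_um, cal)
  expect_identical(x_na$units, "nA")
  expect_equal(x_na$values, 2 * x_um$values + 0.1)
  back <- current_to_concentration(x_na, cal)
  expect_identical(back$units, "uM")
  expect_equal(back$values, x_um$values)
})

test_that("conversion rejects wrong units", {
  cal <- fit_calibration(c(0, 1, 5), c(0, 2, 10))
  x_um <- trace(c(1, 2), 10000, units = "uM")
  expect_error(current_to_concentration(x_um, cal), "nA")
  x_na <- trace(c(1, 2), 10000, units = "nA")
  expect_error(concentration_to_current(x_na, cal), "uM")
})
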