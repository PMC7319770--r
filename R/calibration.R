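#' Fit a carbon-fiber electrode calibration line
#'
#' Electrodes are calibrated by puffing dopamine solutions of increasing
#' concentration (0, 1, 5, 10, 20 uM is the standard ladder) and recording
#' the plateau current at each step. The plateau currents are regressed on
#' concentration by ordinary least squares; only electrodes with a linear
#' relationship (high r-squared) are usable.
#'
#' @param concentration_um dopamine concentrations, uM (>= 2 distinct).
#' @param current_na plateau currents, nA.
#' @param r_squared_min minimum r-squared for a usable electrode
#'   (default 0.98).
#' @return An object of class `"cfe_calibration"` with fields `slope_na_per_um`,
#'   `intercept_na`, `r_squared`, `usable` and the calibration `points`.
#' @export
fit_calibration <- function(concentration_um, current_na, r_squared_min = 0.98) {
  stopifnot(length(concentration_um) == length(current_na))
  if (length(unique(concentration_um)) < 2L)
    stop("calibration needs at least 2 distinct concentrations", call. = FALSE)
  fit <- lm(current_na ~ concentration_um)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((current_na - mean(current_na))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  structure(
    list(points = data.frame(concentration_um = concentration_um,
                             current_na = current_na),
         slope_na_per_um = slope, intercept_na = intercept,
         r_squared = r2,
         usable = is.finite(slope) && slope > 0 && r2 >= r_squared_min),
    class = "cfe_calibration"
  )
}

#' @export
print.cfe_calibration <- function(x, ...) {
  cat(sprintf("<cfe_calibration> slope %.4g nA/uM, intercept %.4g nA, r2 %.4f (%s)\n",
              x$slope_na_per_um, x$intercept_na, x$r_squared,
              if (x$usable) "usable" else "NOT usable"))
  invisible(x)
}

#' Convert a current trace to dopamine concentration
#'
#' Inverts the calibration line elementwise:
#' `concentration = (current - intercept) / slope`.
#'
#' @param x a [trace()] in nA.
#' @param cal a [fit_calibration()] result with positive slope.
#' @return A [trace()] in uM; the calibration used is recorded in the
#'   trace metadata.
#' @export
current_to_concentration <- function(x, cal) {
  stopifnot(inherits(x, "trace"), inherits(cal, "cfe_calibration"))
  if (x$units != "nA") stop("trace must be in nA", call. = FALSE)
  if (!is.finite(cal$slope_na_per_um) || cal$slope_na_per_um <= 0)
    stop("calibration slope must be > 0", call. = FALSE)
  x$values <- (x$values - cal$intercept_na) / cal$slope_na_per_um
  x$units <- "uM"
  x$metadata$calibration <- list(slope_na_per_um = cal$slope_na_per_um,
                                 intercept_na = cal$intercept_na,
                                 r_squared = cal$r_squared)
  x
}

#' Convert a concentration trace to current
#'
#' Forward application of the calibration line; the inverse of
#' [current_to_concentration()].
#'
#' @inheritParams current_to_concentration
#' @param x a [trace()] in uM.
#' @return A [trace()] in nA.
#' @export
concentration_to_current <- function(x, cal) {
  stopifnot(inherits(x, "trace"), inherits(cal, "cfe_calibration"))
  if (x$units != "uM") stop("trace must be in uM", call. = FALSE)
  x$values <- cal$slope_na_per_um * x$values + cal$intercept_na
  x$units <- "nA"
  x
}
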