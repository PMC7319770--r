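#' Uniformly sampled trace
#'
#' Container for an amperometric current trace or a dopamine concentration
#' trace: a start time, a sampling rate and a numeric vector of values.
#'
#' @param values numeric vector of samples, length >= 2, all finite.
#' @param sampling_rate_hz samples per second (10000 for standard
#'   amperometric acquisition).
#' @param units one of `"nA"` (current) or `"uM"` (dopamine concentration).
#' @param start_time_s time of the first sample, seconds.
#' @return An object of class `"trace"`.
#' @export
trace <- function(values, sampling_rate_hz = 10000, units = c("uM", "nA"),
                  start_time_s = 0) {
  units <- match.arg(units)
  assert_scalar_num(sampling_rate_hz, "sampling_rate_hz")
  assert_scalar_num(start_time_s, "start_time_s")
  if (sampling_rate_hz <= 0) stop("`sampling_rate_hz` must be > 0", call. = FALSE)
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a trace needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(values))) stop("trace values must be finite", call. = FALSE)
  structure(
    list(values = values, sampling_rate_hz = sampling_rate_hz,
         start_time_s = start_time_s, units = units, metadata = list()),
    class = "trace"
  )
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ %g Hz, %s, t0 = %g s, range [%.4g, %.4g]\n",
              length(x$values), x$sampling_rate_hz, x$units, x$start_time_s,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Sample times of a trace
#' @param x a [trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace"))
  x$start_time_s + (seq_along(x$values) - 1) / x$sampling_rate_hz
}

# index of the sample at or immediately before time t
.time_to_index <- function(x, t) {
  i <- floor((t - x$start_time_s) * x$sampling_rate_hz + 1e-9) + 1
  as.integer(i)
}

.window_indices <- function(x, start_s, end_s, what = "window") {
  n <- length(x$values)
  i0 <- .time_to_index(x, start_s)
  i1 <- .time_to_index(x, end_s)
  if (i0 < 1L || i1 > n || i1 < i0)
    stop(sprintf("%s [%g, %g] s falls outside the trace", what, start_s, end_s),
         call. = FALSE)
  i0:i1
}

.baseline_level <- function(x, baseline_window) {
  idx <- .window_indices(x, baseline_window[1], baseline_window[2], "baseline window")
  mean(x$values[idx])
}

#' Pointwise average of repeated sweeps
#'
#' Averages repeated stimulus-locked recordings ("average of four sweeps")
#' sample by sample.
#'
#' @param traces list of [trace()] objects with identical length, sampling
#'   rate and units.
#' @return A [trace()] holding the pointwise mean.
#' @export
average_sweeps <- function(traces) {
  if (!is.list(traces) || length(traces) < 1L || !all(vapply(traces, inherits, TRUE, "trace")))
    stop("`traces` must be a non-empty list of trace objects", call. = FALSE)
  n <- length(traces[[1]]$values)
  fs <- traces[[1]]$sampling_rate_hz
  un <- traces[[1]]$units
  for (tr in traces) {
    if (length(tr$values) != n) stop("sweeps have mismatched lengths", call. = FALSE)
    if (tr$sampling_rate_hz != fs) stop("sweeps have mismatched sampling rates", call. = FALSE)
    if (tr$units != un) stop("sweeps have mismatched units", call. = FALSE)
  }
  vals <- rowMeans(vapply(traces, function(tr) tr$values, numeric(n)))
  out <- traces[[1]]
  out$values <- vals
  out
}

#' Blank and interpolate over stimulus artefacts
#'
#' Electrical/optical stimulation leaves brief artefacts on amperometric
#' recordings; quantification is done "after removal of the stimulus
#' artefacts". Samples within `[onset, onset + blank_window_ms]` of each
#' stimulus are replaced by linear interpolation between the flanking
#' retained samples.
#'
#' @param x a [trace()].
#' @param stims a [stimulus_train()].
#' @param blank_window_ms blanking window per stimulus, milliseconds
#'   (default 1 ms).
#' @return The trace with artefact windows interpolated.
#' @export
remove_stimulus_artefacts <- function(x, stims, blank_window_ms = 1.0) {
  stopifnot(inherits(x, "trace"), inherits(stims, "stimulus_train"))
  assert_scalar_num(blank_window_ms, "blank_window_ms")
  if (blank_window_ms * 1e-3 < 1 / x$sampling_rate_hz)
    stop("blank window must cover at least one sample", call. = FALSE)
  if (length(stims$onset_times_s) == 0L) return(x)
  vals <- x$values
  n <- length(vals)
  keep <- rep(TRUE, n)
  for (on in stims$onset_times_s) {
    idx <- .window_indices(x, on, on + blank_window_ms * 1e-3, "blank window")
    keep[idx] <- FALSE
  }
  if (!keep[1] || !keep[n])
    stop("blank window extends beyond the trace", call. = FALSE)
  ti <- trace_times(x)
  vals[!keep] <- approx(ti[keep], vals[keep], xout = ti[!keep])$y
  x$values <- vals
  x
}

#' Stimulus train description
#'
#' @param onset_times_s strictly increasing stimulus onset times, seconds.
#' @param pulse_duration_ms pulse duration, milliseconds (1 ms light pulses
#'   by default).
#' @return An object of class `"stimulus_train"`.
#' @export
stimulus_train <- function(onset_times_s, pulse_duration_ms = 1.0) {
  onset_times_s <- as.numeric(onset_times_s)
  if (length(onset_times_s) > 1L && any(diff(onset_times_s) <= 0))
    stop("stimulus onsets must be strictly increasing", call. = FALSE)
  assert_scalar_num(pulse_duration_ms, "pulse_duration_ms")
  if (pulse_duration_ms <= 0) stop("`pulse_duration_ms` must be > 0", call. = FALSE)
  structure(list(onset_times_s = onset_times_s,
                 pulse_duration_ms = pulse_duration_ms),
            class = "stimulus_train")
}

#' Peak amplitude above baseline
#'
#' Maximum of the trace in a search window minus the mean over a preceding
#' baseline window. Negative values (flat or noisy traces) are reported
#' as-is.
#'
#' @param x a [trace()] in concentration units.
#' @param search_window `(start_s, end_s)` window searched for the peak.
#' @param baseline_window `(start_s, end_s)` pre-stimulus window averaged
#'   for the baseline.
#' @return Peak amplitude in the trace's units.
#' @export
peak_amplitude <- function(x, search_window, baseline_window) {
  stopifnot(inherits(x, "trace"), length(search_window) == 2L,
            length(baseline_window) == 2L)
  if (baseline_window[2] > search_window[1])
    stop("baseline window must precede the search window", call. = FALSE)
  idx <- .window_indices(x, search_window[1], search_window[2], "search window")
  max(x$values[idx]) - .baseline_level(x, baseline_window)
}

#' 20-80% rise time
#'
#' Time between the baseline-corrected signal's first upward crossing of 20%
#' and of 80% of its post-onset peak, with linear interpolation between
#' bracketing samples (sub-sample resolution). The reference peak level is
#' read from a copy smoothed with a short centered moving average
#' (`peak_window_ms`), which keeps the 20%/80% levels from tracking the
#' maximum noise excursion; the crossings themselves are found on the raw
#' signal. Returned in milliseconds.
#'
#' @param x a [trace()].
#' @param onset_s stimulus onset time, seconds; the peak is searched after
#'   this time.
#' @param baseline_window `(start_s, end_s)` pre-onset baseline window.
#' @param search_end_s optional end of the peak search window (defaults to
#'   the end of the trace).
#' @param peak_window_ms width of the moving average used only to determine
#'   the peak level (default 1 ms; 0 disables smoothing).
#' @return Rise time in milliseconds.
#' @export
rise_time_20_80 <- function(x, onset_s, baseline_window, search_end_s = NULL,
                            peak_window_ms = 1.0) {
  stopifnot(inherits(x, "trace"))
  if (is.null(search_end_s))
    search_end_s <- x$start_time_s + (length(x$values) - 1) / x$sampling_rate_hz
  base <- .baseline_level(x, baseline_window)
  idx <- .window_indices(x, onset_s, search_end_s, "search window")
  v <- x$values[idx] - base
  ti <- trace_times(x)[idx]
  w <- max(1L, round(peak_window_ms * 1e-3 * x$sampling_rate_hz))
  vsm <- if (w > 1L && length(v) > w)
    as.numeric(stats::filter(v, rep(1 / w, w), sides = 2)) else v
  pk <- max(vsm, na.rm = TRUE)
  if (pk <= 0) stop("no positive peak after onset", call. = FALSE)
  ipk <- which.max(vsm)
  t_cross <- function(level) {
    # first upward crossing before (or at) the peak
    seg <- v[1:ipk]
    above <- which(seg >= level)
    if (length(above) == 0L) stop("level never reached before peak", call. = FALSE)
    i <- above[1]
    if (i == 1L) return(ti[1])
    # linear interpolation between bracketing samples
    t0 <- ti[i - 1]; t1 <- ti[i]
    v0 <- seg[i - 1]; v1 <- seg[i]
    t0 + (level - v0) / (v1 - v0) * (t1 - t0)
  }
  t20 <- t_cross(0.20 * pk)
  t80 <- t_cross(0.80 * pk)
  (t80 - t20) * 1000
}

#' Area under the curve over a window
#'
#' Trapezoidal integral of the (optionally baseline-corrected) trace over
#' `[start_s, start_s + duration_s]`. The standard train window integrates
#' from the first stimulus onset for 2.935 s and is expressed in uM x s.
#'
#' @param x a [trace()].
#' @param start_s window start, seconds.
#' @param duration_s window length, seconds (2.935 s for 10 Hz trains).
#' @param baseline_window optional `(start_s, end_s)` baseline window; if
#'   `NULL` no baseline is subtracted.
#' @return Area in value-units times seconds.
#' @export
area_under_curve <- function(x, start_s, duration_s = 2.935,
                             baseline_window = NULL) {
  stopifnot(inherits(x, "trace"))
  assert_scalar_num(duration_s, "duration_s", lower = 0)
  idx <- .window_indices(x, start_s, start_s + duration_s, "integration window")
  base <- if (is.null(baseline_window)) 0 else .baseline_level(x, baseline_window)
  ti <- trace_times(x)[idx]
  pracma::trapz(ti, x$values[idx] - base)
}

#' Per-stimulus amplitudes across a train
#'
#' Measures each stimulus response relative to the trace value immediately
#' preceding its onset (local baseline), so summating responses are not
#' double-counted, and normalizes by a reference first amplitude (the mean
#' first amplitude of the control group in genotype comparisons).
#'
#' @param x a [trace()] in concentration units.
#' @param stims a [stimulus_train()].
#' @param reference_first_amplitude positive reference amplitude used for
#'   normalization.
#' @return A list with `amplitudes_um` and `normalized`, one entry per
#'   stimulus.
#' @export
train_amplitudes <- function(x, stims, reference_first_amplitude) {
  stopifnot(inherits(x, "trace"), inherits(stims, "stimulus_train"))
  assert_scalar_num(reference_first_amplitude, "reference_first_amplitude")
  if (reference_first_amplitude <= 0)
    stop("`reference_first_amplitude` must be > 0", call. = FALSE)
  ons <- stims$onset_times_s
  if (length(ons) == 0L) stop("no stimuli in the train", call. = FALSE)
  t_end <- x$start_time_s + (length(x$values) - 1) / x$sampling_rate_hz
  ends <- c(ons[-1], t_end)
  amps <- numeric(length(ons))
  for (k in seq_along(ons)) {
    i_on <- .time_to_index(x, ons[k])
    if (i_on < 1L) stop("stimulus before trace start", call. = FALSE)
    local_base <- x$values[max(1L, i_on)]
    idx <- .window_indices(x, ons[k], ends[k], "inter-stimulus window")
    amps[k] <- max(x$values[idx]) - local_base
  }
  list(amplitudes_um = amps, normalized = amps / reference_first_amplitude)
}

#' Uptake-blocker (DAT block) comparison of two train responses
#'
#' Compares dopamine release before and during dopamine-transporter block
#' (e.g. nomifensine): the total increase is the area difference
#' (drug - baseline) and the fold increase is the area ratio
#' (drug / baseline), both over the same integration window.
#'
#' @param baseline a [trace()] recorded before the drug.
#' @param drug a [trace()] recorded during the drug.
#' @param window `(start_s, duration_s)` integration window shared by both
#'   traces (default duration 2.935 s).
#' @param baseline_window optional `(start_s, end_s)` pre-stimulus baseline
#'   window applied to both traces.
#' @return A list with `area_baseline`, `area_drug`, `subtracted_area` and
#'   `fold_increase` (`NA` when the baseline area is not positive).
#' @export
dat_block_comparison <- function(baseline, drug, window = c(0, 2.935),
                                 baseline_window = NULL) {
  a0 <- area_under_curve(baseline, window[1], window[2], baseline_window)
  a1 <- area_under_curve(drug, window[1], window[2], baseline_window)
  list(area_baseline = a0, area_drug = a1,
       subtracted_area = a1 - a0,
       fold_increase = if (a0 > 0) a1 / a0 else NA_real_)
}

#' KCl puff response
#'
#' Peak amplitude and area under the curve from the start of KCl
#' application to 200 s after the end of the puff, baseline taken from a
#' pre-puff window.
#'
#' @param x a [trace()] in concentration units.
#' @param puff_start_s start of the KCl application, seconds.
#' @param puff_duration_s duration of the puff (10 s standard).
#' @param post_s window length after the puff (200 s standard).
#' @param baseline_window optional `(start_s, end_s)` pre-puff baseline
#'   window; defaults to the 10 s before the puff (clipped to the trace).
#' @return A list with `peak_um` and `auc_um_s`.
#' @export
kcl_response <- function(x, puff_start_s, puff_duration_s = 10,
                         post_s = 200, baseline_window = NULL) {
  stopifnot(inherits(x, "trace"))
  if (is.null(baseline_window)) {
    b0 <- max(x$start_time_s, puff_start_s - 10)
    baseline_window <- c(b0, puff_start_s)
  }
  end_s <- puff_start_s + puff_duration_s + post_s
  idx <- .window_indices(x, puff_start_s, end_s, "KCl window")
  base <- .baseline_level(x, baseline_window)
  ti <- trace_times(x)[idx]
  v <- x$values[idx] - base
  list(peak_um = max(v), auc_um_s = pracma::trapz(ti, v))
}

#' Normalize a microdialysis time series
#'
#' Divides each concentration by the mean concentration over a reference
#' window (the 76th-120th minute of the reference/control group) and also
#' returns a natural-log copy of the normalized values, matching how
#' lognormally distributed in vivo dopamine levels are analysed.
#'
#' @param time_min numeric sampling times, minutes.
#' @param concentration dopamine concentrations at those times.
#' @param reference_window_min `(start, end)` minutes of the reference
#'   window, default `c(76, 120)`.
#' @param reference_mean optional externally supplied reference mean (the
#'   control group's window mean when normalizing another group).
#' @return A list with `normalized`, `log_normalized` and `reference_mean`.
#' @export
normalize_microdialysis <- function(time_min, concentration,
                                    reference_window_min = c(76, 120),
                                    reference_mean = NULL) {
  stopifnot(length(time_min) == length(concentration))
  if (is.null(reference_mean)) {
    inref <- time_min >= reference_window_min[1] & time_min <= reference_window_min[2]
    if (!any(inref)) stop("no samples in the reference window", call. = FALSE)
    reference_mean <- mean(concentration[inref])
  }
  assert_scalar_num(reference_mean, "reference_mean")
  if (reference_mean <= 0) stop("reference mean must be > 0", call. = FALSE)
  normalized <- concentration / reference_mean
  if (any(normalized <= 0))
    stop("non-positive concentrations: natural-log copy undefined", call. = FALSE)
  list(normalized = normalized, log_normalized = log(normalized),
       reference_mean = reference_mean)
}

#' Optional zero-phase low-pass filter
#'
#' Acquisition hardware low-pass filters amperometric signals at 400 Hz;
#' analysis treats that as a property of the recording. For synthetic data
#' this zero-phase Butterworth filter can emulate it. Not applied by
#' default anywhere in the analysis chain.
#'
#' @param x a [trace()].
#' @param cutoff_hz cutoff frequency (default 400 Hz).
#' @param order filter order (default 2).
#' @return The filtered trace.
#' @export
lowpass_trace <- function(x, cutoff_hz = 400, order = 2) {
  stopifnot(inherits(x, "trace"))
  w <- cutoff_hz / (x$sampling_rate_hz / 2)
  if (w <= 0 || w >= 1) stop("cutoff must lie within (0, Nyquist)", call. = FALSE)
  bf <- signal::butter(order, w, type = "low")
  x$values <- as.numeric(signal::filtfilt(bf, x$values))
  x
}
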