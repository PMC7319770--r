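#' Specification of a synthetic dopamine transient recording
#'
#' Describes a stimulus-locked amperometric recording: each stimulus
#' releases a dopamine transient modelled as a peak-normalized difference
#' of exponentials, cleared with a decay constant that an uptake blocker
#' (e.g. nomifensine) would scale up. The concentration trace maps to
#' current through a linear electrode calibration; single-sample stimulus
#' artefacts and Gaussian noise complete the recording.
#'
#' @param duration_s recording length, seconds.
#' @param sampling_rate_hz sampling rate (default 10000, the standard
#'   amperometric acquisition rate).
#' @param stimulus_times_s stimulus onset times within `[0, duration_s]`.
#' @param amplitude_um per-stimulus peak dopamine, uM (recycled to the
#'   number of stimuli).
#' @param tau_rise_ms,tau_decay_ms kinetic constants of the transient;
#'   `tau_rise_ms < tau_decay_ms`.
#' @param clearance_scale multiplier on `tau_decay_ms` emulating slowed
#'   reuptake under DAT block (1 = no block).
#' @param artefact_amplitude_na single-sample current spike added at each
#'   stimulus onset, nA.
#' @param noise_sd_um additive Gaussian noise SD on the concentration, uM.
#' @param calibration_slope_na_per_um,calibration_intercept_na linear map
#'   from concentration to current.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return An object of class `"trace_spec"`.
#' @export
trace_spec <- function(duration_s = 2.0,
                       sampling_rate_hz = 10000,
                       stimulus_times_s = 0.1,
                       amplitude_um = 1.0,
                       tau_rise_ms = 1.0,
                       tau_decay_ms = 60.0,
                       clearance_scale = 1.0,
                       artefact_amplitude_na = 0,
                       noise_sd_um = 0,
                       calibration_slope_na_per_um = 2.0,
                       calibration_intercept_na = 0.0,
                       seed = 1L) {
  assert_scalar_num(sampling_rate_hz, "sampling_rate_hz")
  assert_scalar_num(duration_s, "duration_s")
  if (sampling_rate_hz <= 0) stop("sampling rate must be > 0", call. = FALSE)
  if (duration_s <= 0) stop("duration must be > 0", call. = FALSE)
  if (tau_rise_ms >= tau_decay_ms * clearance_scale)
    stop("tau_rise must be smaller than the (scaled) tau_decay", call. = FALSE)
  if (tau_rise_ms <= 0) stop("tau_rise must be > 0", call. = FALSE)
  if (clearance_scale <= 0) stop("clearance_scale must be > 0", call. = FALSE)
  stimulus_times_s <- sort(as.numeric(stimulus_times_s))
  if (length(stimulus_times_s) &&
      (min(stimulus_times_s) < 0 || max(stimulus_times_s) > duration_s))
    stop("stimulus times must lie within [0, duration]", call. = FALSE)
  if (length(stimulus_times_s) > 1L &&
      min(diff(stimulus_times_s)) < 2 / sampling_rate_hz)
    stop("stimuli closer than two sample periods would alias", call. = FALSE)
  amplitude_um <- rep_len(as.numeric(amplitude_um),
                          max(1L, length(stimulus_times_s)))
  if (any(amplitude_um < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (noise_sd_um < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(
    duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
    stimulus_times_s = stimulus_times_s, amplitude_um = amplitude_um,
    tau_rise_ms = tau_rise_ms, tau_decay_ms = tau_decay_ms,
    clearance_scale = clearance_scale,
    artefact_amplitude_na = artefact_amplitude_na,
    noise_sd_um = noise_sd_um,
    calibration_slope_na_per_um = calibration_slope_na_per_um,
    calibration_intercept_na = calibration_intercept_na,
    seed = as.integer(seed)
  ), class = "trace_spec")
}

#' Closed-form dopamine transient
#'
#' Evaluates the peak-normalized difference-of-exponentials transient
#' `A * k * (exp(-t/tau_decay) - exp(-t/tau_rise))` for `t >= 0` (0 before),
#' where `k` normalizes the peak to `A`.
#'
#' @param t_s times relative to stimulus onset, seconds.
#' @param amplitude_um peak amplitude, uM.
#' @param tau_rise_ms,tau_decay_ms kinetic constants, milliseconds.
#' @return Concentration values, uM.
#' @export
dopamine_transient <- function(t_s, amplitude_um, tau_rise_ms, tau_decay_ms) {
  tr <- tau_rise_ms * 1e-3
  td <- tau_decay_ms * 1e-3
  if (tr >= td) stop("tau_rise must be < tau_decay", call. = FALSE)
  tpk <- tr * td / (td - tr) * log(td / tr)
  k <- 1 / (exp(-tpk / td) - exp(-tpk / tr))
  out <- numeric(length(t_s))
  pos <- t_s >= 0
  out[pos] <- amplitude_um * k * (exp(-t_s[pos] / td) - exp(-t_s[pos] / tr))
  out
}

#' Analytic area of a single dopamine transient
#'
#' Integral of [dopamine_transient()] over `[0, Inf)`:
#' `A * k * (tau_decay - tau_rise)`.
#'
#' @inheritParams dopamine_transient
#' @return Area in uM s.
#' @export
dopamine_transient_auc <- function(amplitude_um, tau_rise_ms, tau_decay_ms) {
  tr <- tau_rise_ms * 1e-3
  td <- tau_decay_ms * 1e-3
  tpk <- tr * td / (td - tr) * log(td / tr)
  k <- 1 / (exp(-tpk / td) - exp(-tpk / tr))
  amplitude_um * k * (td - tr)
}

.noiseless_concentration <- function(spec, t_s) {
  td_ms <- spec$tau_decay_ms * spec$clearance_scale
  conc <- numeric(length(t_s))
  for (j in seq_along(spec$stimulus_times_s)) {
    conc <- conc + dopamine_transient(t_s - spec$stimulus_times_s[j],
                                      spec$amplitude_um[j],
                                      spec$tau_rise_ms, td_ms)
  }
  conc
}

#' Generate a synthetic amperometric recording with ground truth
#'
#' Renders the noiseless concentration trace defined by `spec`, converts it
#' to current through the spec's calibration, adds single-sample stimulus
#' artefacts and Gaussian noise, and computes ground-truth metrics (peak,
#' 20-80% rise time, windowed AUC) from a densely oversampled noiseless
#' evaluation of the kinetic form.
#'
#' @param spec a [trace_spec()].
#' @param auc_window `(start_offset_s, duration_s)` of the truth AUC window
#'   relative to the first stimulus; default starts at the first stimulus
#'   and runs 2.935 s (clipped to the trace).
#' @param oversample dense-grid factor for truth computation (default 20).
#' @return A list with `current` (nA [trace()]), `concentration` (noiseless
#'   uM [trace()]) and `truth` (per-stimulus peaks and rise times, window
#'   AUC, the noiseless dense evaluation grid).
#' @export
generate_trace <- function(spec, auc_window = NULL, oversample = 20L) {
  stopifnot(inherits(spec, "trace_spec"))
  set.seed(spec$seed)
  n <- ceiling(spec$duration_s * spec$sampling_rate_hz) + 1L
  t_s <- (seq_len(n) - 1) / spec$sampling_rate_hz
  conc <- .noiseless_concentration(spec, t_s)

  noisy <- conc + if (spec$noise_sd_um > 0) rnorm(n, 0, spec$noise_sd_um) else 0
  cur <- spec$calibration_slope_na_per_um * noisy + spec$calibration_intercept_na
  for (on in spec$stimulus_times_s) {
    i <- floor(on * spec$sampling_rate_hz + 1e-9) + 1
    cur[i] <- cur[i] + spec$artefact_amplitude_na
  }

  # ground truth on a dense grid of the noiseless kinetic form
  fs_d <- spec$sampling_rate_hz * oversample
  nd <- ceiling(spec$duration_s * fs_d) + 1L
  td_s <- (seq_len(nd) - 1) / fs_d
  dense <- .noiseless_concentration(spec, td_s)

  ons <- spec$stimulus_times_s
  peaks <- rises <- rep(NA_real_, length(ons))
  if (length(ons)) {
    bounds <- c(ons, spec$duration_s)
    for (j in seq_along(ons)) {
      i0 <- which(td_s >= ons[j])[1]
      i1 <- max(which(td_s <= bounds[j + 1]))
      seg <- dense[i0:i1] - dense[i0]
      tseg <- td_s[i0:i1]
      pk <- max(seg)
      peaks[j] <- pk
      if (pk > 0) {
        ipk <- which.max(seg)
        cross <- function(level) {
          i <- which(seg[1:ipk] >= level)[1]
          if (is.na(i) || i == 1L) return(tseg[1])
          tseg[i - 1] + (level - seg[i - 1]) / (seg[i] - seg[i - 1]) *
            (tseg[i] - tseg[i - 1])
        }
        rises[j] <- (cross(0.8 * pk) - cross(0.2 * pk)) * 1000
      }
    }
  }
  if (is.null(auc_window)) auc_window <- c(0, 2.935)
  auc <- NA_real_
  if (length(ons)) {
    a0 <- ons[1] + auc_window[1]
    a1 <- min(a0 + auc_window[2], spec$duration_s)
    sel <- td_s >= a0 & td_s <= a1
    auc <- pracma::trapz(td_s[sel], dense[sel])
  }

  list(
    current = {
      tr <- trace(cur, spec$sampling_rate_hz, units = "nA")
      tr$metadata$spec_seed <- spec$seed
      tr
    },
    concentration = trace(conc, spec$sampling_rate_hz, units = "uM"),
    truth = list(true_peak_um = peaks,
                 true_rise_time_20_80_ms = rises,
                 true_auc_um_s = auc,
                 auc_window = auc_window,
                 dense_time_s = td_s,
                 noiseless_dense = dense)
  )
}
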