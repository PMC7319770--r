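# File I/O and reproducible stage runs. Volumes travel as multi-page TIFF
# with a JSON sidecar carrying channel names, grid shape, voxel size and the
# per-channel intensity scaling used to fit the TIFF [0, 1] range; traces
# travel as `time_s,value` CSV with a JSON sidecar for units and rate.

.sidecar_path <- function(path) paste0(path, ".json")

#' Write a multichannel volume as TIFF + JSON sidecar
#'
#' Pages are ordered channel-major (all z-slices of channel 1, then
#' channel 2, ...). Intensities are affinely mapped into `[0, 1]` for
#' storage; the mapping is recorded in the sidecar and inverted on read.
#'
#' @param volume an [image_volume()].
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  d <- dim(volume$channels[[1]])
  pages <- list()
  scaling <- list()
  for (cn in names(volume$channels)) {
    ch <- volume$channels[[cn]]
    lo <- min(ch); hi <- max(ch)
    scale <- if (hi > lo) hi - lo else 1
    scaling[[cn]] <- list(offset = lo, scale = scale)
    sc <- (ch - lo) / scale
    for (z in seq_len(d[1])) pages[[length(pages) + 1L]] <- sc[z, , ]
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(channels = names(volume$channels), shape_zyx = d,
         voxel_size_um = volume$voxel_size_um, scaling = scaling),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multichannel volume written by [write_volume()]
#'
#' @param path TIFF path with a `<path>.json` sidecar.
#' @param voxel_size_um optional `(z, y, x)` override; when both the
#'   sidecar and an override are present the override wins and the
#'   conflict is recorded in the returned object's `voxel_size_source`.
#' @param channels optional channel names required to be present; an error
#'   names any missing channel.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, voxel_size_um = NULL, channels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta_path <- .sidecar_path(path)
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
  else NULL
  if (is.null(meta))
    stop("missing sidecar metadata: ", meta_path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("cannot parse TIFF: ",
                                             conditionMessage(e), call. = FALSE))
  d <- as.integer(meta$shape_zyx)
  cnames <- meta$channels
  if (length(pages) != d[1] * length(cnames))
    stop("TIFF page count does not match sidecar shape", call. = FALSE)
  if (!is.null(channels)) {
    missing_ch <- setdiff(channels, cnames)
    if (length(missing_ch))
      stop("missing channel(s): ", paste(missing_ch, collapse = ", "),
           call. = FALSE)
  }
  vs_meta <- as.numeric(meta$voxel_size_um)
  source <- "metadata"
  if (!is.null(voxel_size_um)) {
    if (length(vs_meta) == 3L && !isTRUE(all.equal(vs_meta, as.numeric(voxel_size_um))))
      source <- "override (conflicts with metadata)"
    else source <- "override"
    vs <- as.numeric(voxel_size_um)
  } else if (length(vs_meta) == 3L) {
    vs <- vs_meta
  } else {
    stop("no voxel size in metadata and no override given", call. = FALSE)
  }
  chans <- list()
  for (ci in seq_along(cnames)) {
    arr <- array(0, d)
    for (z in seq_len(d[1]))
      arr[z, , ] <- pages[[(ci - 1L) * d[1] + z]]
    sc <- meta$scaling[[cnames[ci]]]
    chans[[cnames[ci]]] <- arr * sc$scale + sc$offset
  }
  out <- image_volume(chans, vs)
  out$voxel_size_source <- source
  out
}

#' Write a trace as CSV + JSON sidecar
#'
#' @param x a [trace()].
#' @param path output CSV path (`time_s,value` header).
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "trace"))
  df <- data.frame(time_s = trace_times(x), value = x$values)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(units = x$units, sampling_rate_hz = x$sampling_rate_hz,
         start_time_s = x$start_time_s),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trace from CSV
#'
#' Expects a `time_s,value` header and uniform sampling: the rate is
#' inferred from the median spacing and rows deviating by more than 1 ppm
#' are reported as errors.
#'
#' @param path CSV path; a `<path>.json` sidecar (if present) supplies the
#'   units, otherwise pass `units`.
#' @param units `"uM"` or `"nA"`, used when there is no sidecar.
#' @return A [trace()].
#' @export
read_trace <- function(path, units = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(read.csv(path), error = function(e)
    stop("cannot parse trace CSV: ", conditionMessage(e), call. = FALSE))
  if (!all(c("time_s", "value") %in% names(df)))
    stop("trace CSV must have columns time_s,value", call. = FALSE)
  if (nrow(df) < 2L) stop("trace CSV needs at least 2 rows", call. = FALSE)
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("trace time must be strictly increasing", call. = FALSE)
  step <- median(dt)
  bad <- which(abs(dt - step) / step > 1e-6)
  if (length(bad))
    stop("non-uniform sampling at rows ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "), call. = FALSE)
  meta_path <- .sidecar_path(path)
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    units <- meta$units
  }
  if (is.null(units)) stop("trace units unknown: no sidecar and no `units`",
                           call. = FALSE)
  trace(df$value, sampling_rate_hz = 1 / step, units = units,
        start_time_s = df$time_s[1])
}

#' Assemble a run configuration record
#'
#' @param stage stage name.
#' @param params named list of stage parameters.
#' @param seed master seed for the run.
#' @return A list of class `"run_config"` including the package version.
#' @export
run_config <- function(stage, params = list(), seed = 1L) {
  structure(list(stage = stage, params = params, seed = as.integer(seed),
                 version = as.character(utils::packageVersion("dopaquant"))),
            class = "run_config")
}

#' Write a tidy metrics table with its run record
#'
#' Metrics rows are keyed by `(run_id, item_id, metric, value, units)`;
#' physical quantities must carry non-empty units. Rows are sorted for
#' deterministic output; the run record (stage, parameters, seed, version)
#' is written alongside as JSON.
#'
#' @param metrics data.frame with columns `run_id`, `item_id`, `metric`,
#'   `value`, `units`.
#' @param run a [run_config()].
#' @param out_prefix output path prefix; writes `<prefix>_metrics.csv` and
#'   `<prefix>_run.json`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_report <- function(metrics, run, out_prefix) {
  stopifnot(is.data.frame(metrics), inherits(run, "run_config"))
  need <- c("run_id", "item_id", "metric", "value", "units")
  if (!all(need %in% names(metrics)))
    stop("metrics must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(metrics) == 0L) stop("empty metrics table", call. = FALSE)
  if (any(!nzchar(metrics$units)))
    stop("every metric needs non-empty units (use \"1\" for dimensionless)",
         call. = FALSE)
  key <- paste(metrics$run_id, metrics$item_id, metrics$metric)
  if (anyDuplicated(key)) stop("duplicate metric keys", call. = FALSE)
  metrics <- metrics[order(key), , drop = FALSE]
  csv_path <- paste0(out_prefix, "_metrics.csv")
  json_path <- paste0(out_prefix, "_run.json")
  write.csv(metrics, csv_path, row.names = FALSE)
  jsonlite::write_json(unclass(run), json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(metrics = csv_path, run = json_path))
}

#' Run one pipeline stage reproducibly
#'
#' Dispatches a named stage with a parameter list, a master seed and an
#' output directory. Each stage derives its own random stream from the
#' master seed via [derive_seed()], writes its outputs deterministically,
#' and can be rerun bit-for-bit.
#'
#' Stages: `"simulate-trace"`, `"simulate-volume"`, `"simulate-puncta"`,
#' `"analyze-trace"`, `"analyze-volume"`, `"analyze-synaptosomes"`.
#'
#' @param stage stage name (above).
#' @param params named list of stage parameters (constructor/function
#'   arguments for the underlying stage; file `path`s for analysis stages).
#' @param seed master seed.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a named character vector of the files written.
#' @export
run_stage <- function(stage, params = list(), seed = 1L, out_dir = ".") {
  stages <- c("simulate-trace", "simulate-volume", "simulate-puncta",
              "analyze-trace", "analyze-volume", "analyze-synaptosomes")
  if (!stage %in% stages)
    stop("unknown stage; use one of: ", paste(stages, collapse = ", "),
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_seed <- derive_seed(seed, stage)
  run <- run_config(stage, params, seed)
  p <- function(...) file.path(out_dir, paste0(...))
  files <- character(0)

  if (stage == "simulate-trace") {
    spec <- do.call(trace_spec, c(params, list(seed = stage_seed)))
    g <- generate_trace(spec)
    write_trace(g$current, p("trace_current.csv"))
    write_trace(g$concentration, p("trace_concentration.csv"))
    jsonlite::write_json(
      list(true_peak_um = g$truth$true_peak_um,
           true_rise_time_20_80_ms = g$truth$true_rise_time_20_80_ms,
           true_auc_um_s = g$truth$true_auc_um_s,
           auc_window = g$truth$auc_window, seed = stage_seed),
      p("trace_truth.json"), auto_unbox = TRUE, digits = NA)
    files <- c(p("trace_current.csv"), p("trace_concentration.csv"),
               p("trace_truth.json"))
  } else if (stage == "simulate-volume") {
    spec <- do.call(volume_spec, c(params, list(seed = stage_seed)))
    g <- generate_volume(spec)
    write_volume(g$volume, p("volume.tif"))
    write.csv(g$truth$clusters, p("volume_truth_clusters.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(true_axon_length_um = g$truth$true_axon_length_um,
           true_th_volume_fraction = g$truth$true_th_volume_fraction,
           n_clusters = nrow(g$truth$clusters), seed = stage_seed),
      p("volume_truth.json"), auto_unbox = TRUE, digits = NA)
    files <- c(p("volume.tif"), p("volume_truth_clusters.csv"),
               p("volume_truth.json"))
  } else if (stage == "simulate-puncta") {
    spec <- do.call(puncta_field_spec, c(params, list(seed = stage_seed)))
    g <- generate_puncta_field(spec)
    vol <- image_volume(lapply(g$channels, function(m)
      array(m, c(1L, dim(m)))), c(1, g$pixel_size_um, g$pixel_size_um))
    write_volume(vol, p("puncta.tif"))
    write.csv(g$truth, p("puncta_truth.csv"), row.names = FALSE)
    files <- c(p("puncta.tif"), p("puncta_truth.csv"))
  } else if (stage == "analyze-trace") {
    x <- read_trace(params$trace_path)
    if (!is.null(params$calibration)) {
      cal <- do.call(fit_calibration, params$calibration)
      if (x$units == "nA") x <- current_to_concentration(x, cal)
    }
    stims <- stimulus_train(params$stim_onsets_s %||% numeric(0))
    if (length(stims$onset_times_s) && isTRUE(params$blank_artefacts))
      x <- remove_stimulus_artefacts(x, stims,
                                     params$artefact_blank_ms %||% 1.0)
    bw <- params$baseline_window
    sw <- params$search_window
    rows <- list()
    add <- function(metric, value, units) rows[[length(rows) + 1L]] <<-
      data.frame(run_id = stage, item_id = basename(params$trace_path),
                 metric = metric, value = value, units = units)
    if (!is.null(sw) && !is.null(bw)) {
      add("peak_amplitude", peak_amplitude(x, sw, bw), "uM")
      add("rise_time_20_80", rise_time_20_80(x, sw[1], bw, sw[2]), "ms")
    }
    if (length(stims$onset_times_s)) {
      add("auc", area_under_curve(x, stims$onset_times_s[1],
                                  params$auc_duration_s %||% 2.935, bw),
          "uM.s")
    }
    metrics <- do.call(rbind, rows)
    files <- write_report(metrics, run, p("trace"))
  } else if (stage == "analyze-volume") {
    vol <- read_volume(params$volume_path,
                       voxel_size_um = params$voxel_size_um)
    cfg_args <- params$config %||% list()
    cfg <- do.call(sim3d_config, c(cfg_args, list(seed = stage_seed)))
    res <- analyze_roi(vol, cfg)
    m <- res$metrics
    metrics <- data.frame(
      run_id = stage, item_id = basename(params$volume_path),
      metric = names(m), value = unlist(m, use.names = FALSE),
      units = c("1", "um/um3", "1/um3", "um3", "1/um3", "um3"))
    files <- write_report(metrics, run, p("volume"))
  } else if (stage == "analyze-synaptosomes") {
    vol <- read_volume(params$image_path,
                       voxel_size_um = params$voxel_size_um)
    px <- vol$voxel_size_um[2]
    chans <- lapply(vol$channels, function(a) a[1, , ])
    res <- analyze_synaptosomes(chans, px)
    write.csv(res$table, p("synaptosome_objects.csv"), row.names = FALSE)
    metrics <- data.frame(
      run_id = stage, item_id = basename(params$image_path),
      metric = c(paste0("n_", res$summary$category),
                 paste0("syt1_fraction_", res$summary$category)),
      value = c(res$summary$n, res$summary$syt1_positive_fraction),
      units = rep("1", 6))
    files <- c(write_report(metrics, run, p("synaptosomes")),
               p("synaptosome_objects.csv"))
  }
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
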