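# 2D confocal synaptosome analysis: rolling-ball background subtraction,
# punctum detection with size/shape thresholds, Bassoon/TH categories and
# Synaptotagmin-1 positivity by an overlap criterion.

#' Rolling-ball background subtraction
#'
#' Estimates the background of a 2D channel by grayscale morphological
#' opening with a disc of the stated physical radius (the classical
#' rolling-ball estimate for structures much smaller than the ball) and
#' subtracts it, clipping at zero. The standard radius is 1 um per channel.
#'
#' @param channel 2D numeric matrix.
#' @param pixel_size_um pixel size, um.
#' @param radius_um ball/disc radius, um (default 1.0); must be >= 1 pixel.
#' @return The background-subtracted channel.
#' @export
rolling_ball_background <- function(channel, pixel_size_um, radius_um = 1.0) {
  stopifnot(is.matrix(channel))
  assert_scalar_num(pixel_size_um, "pixel_size_um")
  r_px <- radius_um / pixel_size_um
  if (r_px < 1) stop("rolling-ball radius smaller than one pixel", call. = FALSE)
  size <- 2L * floor(r_px) + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  bg <- EBImage::opening(channel, brush)
  out <- channel - bg
  out[out < 0] <- 0
  out
}

#' Detect puncta in a background-subtracted channel
#'
#' Applies an Otsu intensity threshold, labels 8-connected components and
#' retains objects passing the size threshold (0.2-1 um^2 inclusive) and
#' the shape threshold (bounding-box axis ratio, larger over smaller,
#' strictly < 1.5).
#'
#' @param channel 2D numeric matrix (after [rolling_ball_background()]).
#' @param pixel_size_um pixel size, um.
#' @param size_range_um2 inclusive area bounds (default `c(0.2, 1)`).
#' @param max_axis_ratio strict upper bound on the bounding-box x:y extent
#'   ratio (default 1.5).
#' @return An object of class `"punctum_set"`: per-object pixel indices,
#'   area, bounding-box extents and centroid, plus grid info and the
#'   detection parameters. Objects failing the filters are dropped;
#'   `n_raw` records the pre-filter count.
#' @export
detect_puncta <- function(channel, pixel_size_um,
                          size_range_um2 = c(0.2, 1),
                          max_axis_ratio = 1.5) {
  stopifnot(is.matrix(channel))
  seg <- otsu_threshold(channel)
  objs3 <- label_components(seg$mask, c(1, pixel_size_um, pixel_size_um), 26L)
  px_area <- pixel_size_um^2
  out <- list()
  for (o in objs3$objects) {
    yy <- o$voxels[, "y"]; xx <- o$voxels[, "x"]
    area <- o$n_voxels * px_area
    ext_x <- diff(range(xx)) + 1L
    ext_y <- diff(range(yy)) + 1L
    ratio <- max(ext_x, ext_y) / min(ext_x, ext_y)
    if (area < size_range_um2[1] || area > size_range_um2[2]) next
    if (ratio >= max_axis_ratio) next
    out[[length(out) + 1L]] <- list(
      label = o$label,
      pixels = cbind(y = yy, x = xx),
      indices_2d = (xx - 1L) * dim(channel)[1] + yy,  # column-major linear
      area_um2 = area, ext_x_px = ext_x, ext_y_px = ext_y,
      axis_ratio = ratio,
      centroid_px = c(y = mean(yy), x = mean(xx)))
  }
  structure(list(objects = out, dim = dim(channel),
                 pixel_size_um = pixel_size_um,
                 threshold = seg$threshold,
                 n_raw = length(objs3$objects),
                 size_range_um2 = size_range_um2,
                 max_axis_ratio = max_axis_ratio),
            class = "punctum_set")
}

#' @export
print.punctum_set <- function(x, ...) {
  cat(sprintf("<punctum_set> %d puncta retained of %d components, %g um/px\n",
              length(x$objects), x$n_raw, x$pixel_size_um))
  invisible(x)
}

.punctum_mask <- function(set) {
  m <- matrix(FALSE, set$dim[1], set$dim[2])
  for (o in set$objects) m[o$indices_2d] <- TRUE
  m
}

#' Categorize puncta and score Synaptotagmin-1 positivity
#'
#' Pairs Bassoon and TH puncta into the mutually exclusive categories
#' Bassoon+TH+, Bassoon-TH+ and Bassoon+TH- (co-positivity decided by
#' pixel overlap relative to the smaller object of the pair, default
#' threshold 20%), then scores each category object Synaptotagmin-1
#' positive when the Syt-1 mask covers between 20% and 100% of the
#' category object's pixels.
#'
#' @param bassoon,th,syt1 [detect_puncta()] results from the same image.
#' @param co_overlap_min Bassoon/TH co-positivity overlap threshold
#'   (fraction of the smaller object, default 0.20).
#' @param syt1_overlap `(min, max)` inclusive Syt-1 overlap criterion as a
#'   fraction of the category object (default `c(0.20, 1)`).
#' @return A list with `table` (one row per category object: category,
#'   area, Syt-1 overlap and positivity) and `summary` (per-category
#'   counts and positive fractions; fraction `NA` for an empty category).
#' @export
categorize_objects <- function(bassoon, th, syt1,
                               co_overlap_min = 0.20,
                               syt1_overlap = c(0.20, 1.0)) {
  stopifnot(inherits(bassoon, "punctum_set"), inherits(th, "punctum_set"),
            inherits(syt1, "punctum_set"),
            identical(bassoon$dim, th$dim), identical(th$dim, syt1$dim))
  dimg <- th$dim
  # label maps for pairwise overlaps
  blab <- matrix(0L, dimg[1], dimg[2])
  for (j in seq_along(bassoon$objects))
    blab[bassoon$objects[[j]]$indices_2d] <- j
  syt1_mask <- .punctum_mask(syt1)

  rows <- list()
  matched_b <- logical(length(bassoon$objects))
  add_row <- function(category, pix_idx, area) {
    ov <- mean(syt1_mask[pix_idx])
    rows[[length(rows) + 1L]] <<- data.frame(
      category = category, area_um2 = area, syt1_overlap = ov,
      syt1_positive = ov >= syt1_overlap[1] & ov <= syt1_overlap[2])
  }
  for (t_obj in th$objects) {
    hits <- blab[t_obj$indices_2d]
    hits <- hits[hits > 0L]
    partner <- 0L
    if (length(hits)) {
      for (j in unique(hits)) {
        n_ov <- sum(hits == j)
        smaller <- min(length(t_obj$indices_2d),
                       length(bassoon$objects[[j]]$indices_2d))
        if (n_ov / smaller >= co_overlap_min) { partner <- j; break }
      }
    }
    if (partner > 0L) {
      matched_b[partner] <- TRUE
      pix <- union(t_obj$indices_2d, bassoon$objects[[partner]]$indices_2d)
      add_row("Bassoon+TH+", pix,
              length(pix) * th$pixel_size_um^2)
    } else {
      add_row("Bassoon-TH+", t_obj$indices_2d, t_obj$area_um2)
    }
  }
  for (j in seq_along(bassoon$objects)) {
    if (matched_b[j]) next
    b_obj <- bassoon$objects[[j]]
    add_row("Bassoon+TH-", b_obj$indices_2d, b_obj$area_um2)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(0), area_um2 = numeric(0),
               syt1_overlap = numeric(0), syt1_positive = logical(0))
  cats <- c("Bassoon+TH+", "Bassoon-TH+", "Bassoon+TH-")
  summary <- data.frame(
    category = cats,
    n = vapply(cats, function(cc) sum(tab$category == cc), 1L),
    syt1_positive_fraction = vapply(cats, function(cc) {
      sel <- tab$category == cc
      if (!any(sel)) NA_real_ else mean(tab$syt1_positive[sel])
    }, 1)
  )
  rownames(summary) <- NULL
  list(table = tab, summary = summary)
}

#' Analyze a three-channel synaptosome image
#'
#' Convenience wrapper: rolling-ball background subtraction, punctum
#' detection per channel, categorization and Syt-1 positivity.
#'
#' @param channels named list with 2D matrices `bassoon`, `syt1`, `th`.
#' @param pixel_size_um pixel size, um.
#' @param rolling_ball_radius_um background-subtraction radius (default 1).
#' @param ... passed on to [detect_puncta()] and [categorize_objects()].
#' @return The [categorize_objects()] result, plus the per-channel
#'   punctum sets.
#' @export
analyze_synaptosomes <- function(channels, pixel_size_um,
                                 rolling_ball_radius_um = 1.0, ...) {
  stopifnot(all(c("bassoon", "syt1", "th") %in% names(channels)))
  dots <- list(...)
  det_args <- dots[names(dots) %in% c("size_range_um2", "max_axis_ratio")]
  cat_args <- dots[names(dots) %in% c("co_overlap_min", "syt1_overlap")]
  sets <- lapply(channels[c("bassoon", "syt1", "th")], function(ch) {
    sub <- rolling_ball_background(ch, pixel_size_um, rolling_ball_radius_um)
    do.call(detect_puncta, c(list(sub, pixel_size_um), det_args))
  })
  res <- do.call(categorize_objects,
                 c(list(sets$bassoon, sets$th, sets$syt1), cat_args))
  c(res, list(puncta = sets))
}
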