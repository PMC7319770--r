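#' Specification of a synthetic synaptosome punctum field
#'
#' Describes a three-channel 2D image (Bassoon, Syt-1, TH) of round,
#' non-touching puncta in the three mutually exclusive categories
#' Bassoon+TH+, Bassoon-TH+ and Bassoon+TH-, each with a planted fraction
#' of Synaptotagmin-1-positive objects (a Syt-1 punctum concentric with
#' the object), degraded by Gaussian blur and noise.
#'
#' @param image_shape_px `(ny, nx)` image size in pixels.
#' @param pixel_size_um pixel size (default 0.1 um, typical of confocal
#'   synaptosome imaging at 60x with optical zoom).
#' @param n_objects named or positional counts for the categories
#'   `c(bassoon_th = ..., th_only = ..., bassoon_only = ...)`.
#' @param punctum_area_range_um2 `(min, max)` punctum areas (default
#'   `c(0.25, 0.9)`, inside the 0.2-1 um^2 detection window).
#' @param syt1_positive_fraction per-category Syt-1-positive fractions,
#'   recycled to length 3 (order as `n_objects`).
#' @param psf_sigma_um Gaussian blur SD (0 = none).
#' @param noise_sd additive Gaussian noise SD relative to signal peak.
#' @param n_oversize extra planted objects with area above the detection
#'   window (TH channel), used to exercise the size filter.
#' @param n_elongated extra planted bar-shaped objects with bounding-box
#'   axis ratio >= 1.5 (TH channel), used to exercise the shape filter.
#' @param max_place_tries placement attempts per object before failing.
#' @param seed integer seed.
#' @return An object of class `"puncta_field_spec"`.
#' @export
puncta_field_spec <- function(image_shape_px = c(512L, 512L),
                              pixel_size_um = 0.1,
                              n_objects = c(bassoon_th = 40L, th_only = 30L,
                                            bassoon_only = 30L),
                              punctum_area_range_um2 = c(0.25, 0.9),
                              syt1_positive_fraction = c(0.6, 0.6, 0.6),
                              psf_sigma_um = 0,
                              noise_sd = 0,
                              n_oversize = 0L,
                              n_elongated = 0L,
                              max_place_tries = 200L,
                              seed = 1L) {
  image_shape_px <- as.integer(image_shape_px)
  stopifnot(length(image_shape_px) == 2L, all(image_shape_px >= 16L))
  assert_scalar_num(pixel_size_um, "pixel_size_um")
  if (pixel_size_um <= 0) stop("pixel size must be > 0", call. = FALSE)
  n_objects <- as.integer(rep_len(n_objects, 3L))
  if (any(n_objects < 0)) stop("object counts must be >= 0", call. = FALSE)
  if (diff(punctum_area_range_um2) < 0 || any(punctum_area_range_um2 <= 0))
    stop("`punctum_area_range_um2` must be ordered and positive", call. = FALSE)
  syt1_positive_fraction <- rep_len(as.numeric(syt1_positive_fraction), 3L)
  if (any(syt1_positive_fraction < 0 | syt1_positive_fraction > 1))
    stop("Syt-1 positive fractions must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(
    image_shape_px = image_shape_px, pixel_size_um = pixel_size_um,
    n_objects = n_objects,
    punctum_area_range_um2 = punctum_area_range_um2,
    syt1_positive_fraction = syt1_positive_fraction,
    psf_sigma_um = psf_sigma_um, noise_sd = noise_sd,
    n_oversize = as.integer(n_oversize), n_elongated = as.integer(n_elongated),
    max_place_tries = as.integer(max_place_tries), seed = as.integer(seed)
  ), class = "puncta_field_spec")
}

# pixel indices of an axis-aligned ellipse; returns linear (column-major)
# indices or NULL when empty
.ellipse_pixels <- function(cy, cx, ry, rx, ny, nx) {
  y0 <- max(1L, floor(cy - ry)); y1 <- min(ny, ceiling(cy + ry))
  x0 <- max(1L, floor(cx - rx)); x1 <- min(nx, ceiling(cx + rx))
  if (y0 > y1 || x0 > x1) return(NULL)
  g <- expand.grid(y = y0:y1, x = x0:x1)
  inside <- ((g$y - cy) / ry)^2 + ((g$x - cx) / rx)^2 <= 1
  if (!any(inside)) return(NULL)
  (g$x[inside] - 1L) * ny + g$y[inside]
}

.gaussian_blur2 <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-half):half)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  d <- dim(m)
  m <- .convolve_dim1(as.numeric(m), c(d[1], d[2], 1L), k)
  m <- matrix(m, d[1], d[2])
  m <- t(matrix(.convolve_dim1(as.numeric(t(m)), c(d[2], d[1], 1L), k),
                d[2], d[1]))
  m
}

#' Generate a synthetic synaptosome field with ground truth
#'
#' Places the requested numbers of category puncta at non-overlapping
#' positions (minimum center separation keeps distinct objects from
#' touching), renders them into the Bassoon/Syt-1/TH channels, plants
#' Syt-1 puncta concentric with a per-category Bernoulli fraction of the
#' objects, and optionally adds out-of-range objects for filter testing.
#'
#' @param spec a [puncta_field_spec()].
#' @return A list with `channels` (named 2D matrices `bassoon`, `syt1`,
#'   `th`), `pixel_size_um` and `truth` (one row per planted object:
#'   category, rendered area, Syt-1 positivity, and an `out_of_range`
#'   flag for planted filter-violating objects).
#' @export
generate_puncta_field <- function(spec) {
  stopifnot(inherits(spec, "puncta_field_spec"))
  set.seed(spec$seed)
  ny <- spec$image_shape_px[1]; nx <- spec$image_shape_px[2]
  px <- spec$pixel_size_um
  ch <- list(bassoon = matrix(0, ny, nx), syt1 = matrix(0, ny, nx),
             th = matrix(0, ny, nx))
  placed <- data.frame(cy = numeric(0), cx = numeric(0), r = numeric(0))
  truth <- list()

  draw_radii <- function(area_um2) {
    # mild ellipticity keeps the bounding-box ratio clear of the 1.5 cutoff
    ratio <- runif(1, 1.0, 1.2)
    r_um <- sqrt(area_um2 / (pi * ratio))
    c(ry = r_um * ratio / px, rx = r_um / px)
  }
  place_centre <- function(r_px) {
    for (try in seq_len(spec$max_place_tries)) {
      cy <- runif(1, r_px + 2, ny - r_px - 1)
      cx <- runif(1, r_px + 2, nx - r_px - 1)
      if (nrow(placed) == 0L ||
          all(sqrt((placed$cy - cy)^2 + (placed$cx - cx)^2) >
              placed$r + r_px + 3)) return(c(cy, cx))
    }
    stop("cannot place objects without overlap: too many for the field",
         call. = FALSE)
  }
  categories <- c("Bassoon+TH+", "Bassoon-TH+", "Bassoon+TH-")
  chan_of <- list(c("bassoon", "th"), "th", "bassoon")
  for (k in 1:3) {
    n <- spec$n_objects[k]
    if (n == 0L) next
    pos <- rbinom(n, 1L, spec$syt1_positive_fraction[k]) == 1L
    for (i in seq_len(n)) {
      area <- runif(1, spec$punctum_area_range_um2[1],
                    spec$punctum_area_range_um2[2])
      r <- draw_radii(area)
      cc <- place_centre(max(r))
      pix <- .ellipse_pixels(cc[1], cc[2], r["ry"], r["rx"], ny, nx)
      for (cn in chan_of[[k]]) ch[[cn]][pix] <- 1
      if (pos[i]) ch$syt1[pix] <- 1   # concentric, fully covering Syt-1 punctum
      placed[nrow(placed) + 1L, ] <- c(cc[1], cc[2], max(r))
      truth[[length(truth) + 1L]] <- data.frame(
        category = categories[k], cy_px = cc[1], cx_px = cc[2],
        area_um2 = length(pix) * px^2, syt1_positive = pos[i],
        out_of_range = FALSE)
    }
  }
  # planted filter violations (TH channel)
  for (i in seq_len(spec$n_oversize)) {
    area <- spec$punctum_area_range_um2[2] * 2 + 0.5   # clearly above 1 um^2
    r <- sqrt(area / pi) / px
    cc <- place_centre(r)
    pix <- .ellipse_pixels(cc[1], cc[2], r, r, ny, nx)
    ch$th[pix] <- 1
    placed[nrow(placed) + 1L, ] <- c(cc[1], cc[2], r)
    truth[[length(truth) + 1L]] <- data.frame(
      category = "Bassoon-TH+", cy_px = cc[1], cx_px = cc[2],
      area_um2 = length(pix) * px^2, syt1_positive = FALSE,
      out_of_range = TRUE)
  }
  for (i in seq_len(spec$n_elongated)) {
    # bar with bounding-box ratio 2, area inside the size window
    area <- mean(spec$punctum_area_range_um2)
    rx <- sqrt(area / (2 * pi)) / px
    ry <- 2 * rx
    cc <- place_centre(ry)
    pix <- .ellipse_pixels(cc[1], cc[2], ry, rx, ny, nx)
    ch$th[pix] <- 1
    placed[nrow(placed) + 1L, ] <- c(cc[1], cc[2], ry)
    truth[[length(truth) + 1L]] <- data.frame(
      category = "Bassoon-TH+", cy_px = cc[1], cx_px = cc[2],
      area_um2 = length(pix) * px^2, syt1_positive = FALSE,
      out_of_range = TRUE)
  }

  sigma_px <- spec$psf_sigma_um / px
  for (cn in names(ch)) {
    if (sigma_px > 0) ch[[cn]] <- .gaussian_blur2(ch[[cn]], sigma_px)
    if (spec$noise_sd > 0)
      ch[[cn]] <- ch[[cn]] + matrix(rnorm(ny * nx, 0, spec$noise_sd), ny, nx)
  }
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(category = character(0), cy_px = numeric(0), cx_px = numeric(0),
               area_um2 = numeric(0), syt1_positive = logical(0),
               out_of_range = logical(0))
  list(channels = ch, pixel_size_um = px, truth = truth_df)
}
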