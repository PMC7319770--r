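#' Multichannel 3D image volume
#'
#' Container for reconstructed superresolution volumes: named channels
#' (axon marker such as TH, cluster marker such as Bassoon) as 3D arrays
#' with `dim = c(nz, ny, nx)`, plus the physical voxel size.
#'
#' @param channels named list of 3D numeric arrays of identical dimension.
#' @param voxel_size_um `(z, y, x)` voxel size in um.
#' @return An object of class `"image_volume"`.
#' @export
image_volume <- function(channels, voxel_size_um) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  d <- dim(channels[[1]])
  if (length(d) != 3L) stop("channels must be 3D arrays", call. = FALSE)
  for (ch in channels)
    if (!identical(dim(ch), d)) stop("all channels must share one shape", call. = FALSE)
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stop("`voxel_size_um` must be three positive numbers (z, y, x)", call. = FALSE)
  structure(list(channels = channels, voxel_size_um = voxel_size_um),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_volume> %d x %d x %d voxels (z,y,x), %s um, channels: %s\n",
              d[1], d[2], d[3], paste(signif(x$voxel_size_um, 3), collapse = " x "),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Specification of a synthetic axon/cluster volume
#'
#' Describes a two-channel 3D scene: tubular dopamine axons (random-walk
#' centerlines with fixed step and Gaussian angular jitter, rendered as
#' tubes of fixed radius) and ellipsoidal release-site clusters placed
#' either along the axons or as a Poisson process in the surrounding
#' volume, degraded by Gaussian blur and additive Gaussian noise.
#'
#' @param shape_voxels `(nz, ny, nx)` grid size, each >= 8.
#' @param voxel_size_um `(z, y, x)` voxel size; z defaults to 0.125 um (the
#'   acquisition z-step) and xy to 0.04 um (typical reconstructed lateral
#'   pixel of the instrument class).
#' @param n_axons number of axons.
#' @param axon_radius_um tube radius; must resolve to >= 1 voxel per axis.
#' @param axon_step_um centerline segment length.
#' @param axon_bend_sd_rad SD of per-step direction jitter, radians.
#' @param axon_length_um target centerline length per axon. Walks reflect
#'   off the volume faces (the imaged region intersects axons that continue
#'   beyond it) until this length is laid down. Default `NULL` uses 1.5 times
#'   the longest volume extent, which keeps the axon channel's foreground
#'   fraction high enough for histogram-based thresholding to be well posed.
#' @param cluster_rate_inside expected clusters per um of axon length.
#' @param cluster_rate_outside expected clusters per um^3 of non-axon volume.
#' @param cluster_volume_range_um3 `(min, max)` cluster volumes (inside
#'   clusters; also used outside unless overridden).
#' @param cluster_volume_range_outside_um3 optional separate `(min, max)`
#'   for outside clusters, e.g. to plant smaller release-site clusters
#'   inside axons than elsewhere.
#' @param psf_sigma_um `(z, y, x)` Gaussian blur SDs (0 = no blur).
#' @param noise_sd additive Gaussian noise SD relative to the signal peak.
#' @param seed integer seed.
#' @return An object of class `"volume_spec"`.
#' @export
volume_spec <- function(shape_voxels = c(24L, 200L, 200L),
                        voxel_size_um = c(0.125, 0.04, 0.04),
                        n_axons = 2L,
                        axon_radius_um = 0.25,
                        axon_step_um = 0.5,
                        axon_bend_sd_rad = 0.25,
                        axon_length_um = NULL,
                        cluster_rate_inside = 1.0,
                        cluster_rate_outside = 0.3,
                        cluster_volume_range_um3 = c(0.005, 0.035),
                        cluster_volume_range_outside_um3 = NULL,
                        psf_sigma_um = c(0, 0, 0),
                        noise_sd = 0,
                        seed = 1L) {
  shape_voxels <- as.integer(shape_voxels)
  if (length(shape_voxels) != 3L || any(shape_voxels < 8L))
    stop("`shape_voxels` must be three integers >= 8", call. = FALSE)
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stop("voxel sizes must be > 0", call. = FALSE)
  if (axon_radius_um <= 0 || axon_step_um <= 0)
    stop("axon radius and step must be > 0", call. = FALSE)
  if (n_axons > 0 && axon_radius_um < max(voxel_size_um))
    stop("axon radius smaller than one voxel in some axis is unresolvable",
         call. = FALSE)
  extent <- shape_voxels * voxel_size_um
  if (n_axons > 0 && max(extent) < axon_step_um)
    stop("volume too small to contain one axon step", call. = FALSE)
  if (is.null(axon_length_um)) axon_length_um <- 1.5 * max(extent)
  if (axon_length_um <= 0)
    stop("`axon_length_um` must be > 0", call. = FALSE)
  if (diff(cluster_volume_range_um3) < 0 || any(cluster_volume_range_um3 <= 0))
    stop("`cluster_volume_range_um3` must be ordered and positive", call. = FALSE)
  if (is.null(cluster_volume_range_outside_um3))
    cluster_volume_range_outside_um3 <- cluster_volume_range_um3
  if (diff(cluster_volume_range_outside_um3) < 0 ||
      any(cluster_volume_range_outside_um3 <= 0))
    stop("`cluster_volume_range_outside_um3` must be ordered and positive",
         call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (cluster_rate_inside < 0 || cluster_rate_outside < 0)
    stop("cluster rates must be >= 0", call. = FALSE)
  psf_sigma_um <- rep_len(as.numeric(psf_sigma_um), 3L)
  if (any(psf_sigma_um < 0)) stop("psf sigmas must be >= 0", call. = FALSE)
  structure(list(
    shape_voxels = shape_voxels, voxel_size_um = voxel_size_um,
    n_axons = as.integer(n_axons), axon_radius_um = axon_radius_um,
    axon_step_um = axon_step_um, axon_bend_sd_rad = axon_bend_sd_rad,
    axon_length_um = axon_length_um,
    cluster_rate_inside = cluster_rate_inside,
    cluster_rate_outside = cluster_rate_outside,
    cluster_volume_range_um3 = cluster_volume_range_um3,
    cluster_volume_range_outside_um3 = cluster_volume_range_outside_um3,
    psf_sigma_um = psf_sigma_um, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "volume_spec")
}

# physical centre coordinates (um) of voxel indices along one axis
.axis_coords <- function(n, step) (seq_len(n) - 1) * step

# Render a tube of given radius around a polyline into a logical mask.
# polyline: matrix with columns (z, y, x) in um.
.render_tube <- function(mask, voxel_size, polyline, radius) {
  d <- dim(mask)
  for (s in seq_len(nrow(polyline) - 1L)) {
    p0 <- polyline[s, ]; p1 <- polyline[s + 1L, ]
    lo <- pmin(p0, p1) - radius
    hi <- pmax(p0, p1) + radius
    i0 <- pmax(1L, floor(lo / voxel_size) + 1L)
    i1 <- pmin(d, ceiling(hi / voxel_size) + 1L)
    if (any(i0 > i1)) next
    zz <- .axis_coords(d[1], voxel_size[1])[i0[1]:i1[1]]
    yy <- .axis_coords(d[2], voxel_size[2])[i0[2]:i1[2]]
    xx <- .axis_coords(d[3], voxel_size[3])[i0[3]:i1[3]]
    g <- expand.grid(z = zz, y = yy, x = xx, KEEP.OUT.ATTRS = FALSE)
    v <- p1 - p0
    len2 <- sum(v^2)
    w <- cbind(g$z - p0[1], g$y - p0[2], g$x - p0[3])
    tt <- if (len2 > 0) pmin(1, pmax(0, (w %*% v) / len2)) else matrix(0, nrow(w))
    dist2 <- (w[, 1] - tt * v[1])^2 + (w[, 2] - tt * v[2])^2 + (w[, 3] - tt * v[3])^2
    inside <- dist2 <= radius^2
    if (any(inside)) {
      sub <- mask[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
      sub[inside] <- TRUE
      mask[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- sub
    }
  }
  mask
}

# Render an axis-scaled ellipsoid; returns updated mask and rendered voxel count.
.render_ellipsoid <- function(mask, voxel_size, centre, semi_axes) {
  d <- dim(mask)
  i0 <- pmax(1L, floor((centre - semi_axes) / voxel_size) + 1L)
  i1 <- pmin(d, ceiling((centre + semi_axes) / voxel_size) + 1L)
  if (any(i0 > i1)) return(list(mask = mask, count = 0L))
  zz <- .axis_coords(d[1], voxel_size[1])[i0[1]:i1[1]]
  yy <- .axis_coords(d[2], voxel_size[2])[i0[2]:i1[2]]
  xx <- .axis_coords(d[3], voxel_size[3])[i0[3]:i1[3]]
  g <- expand.grid(z = zz, y = yy, x = xx, KEEP.OUT.ATTRS = FALSE)
  inside <- ((g$z - centre[1]) / semi_axes[1])^2 +
    ((g$y - centre[2]) / semi_axes[2])^2 +
    ((g$x - centre[3]) / semi_axes[3])^2 <= 1
  cnt <- sum(inside)
  if (cnt > 0) {
    sub <- mask[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
    sub[inside] <- TRUE
    mask[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- sub
  }
  list(mask = mask, count = cnt)
}

# random unit vector
.runit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Random-walk centerline inside the volume extent; returns matrix (z,y,x) um.
# Direction components are damped in proportion to the extent aspect ratio so
# that axons in a thin slab run mostly laterally (as in sectioned tissue).
# The walk reflects off the volume faces (an imaged region intersects axons
# that continue beyond it) and stops once `target_len` um have been laid down.
.walk_centerline <- function(extent, step, bend_sd, radius, target_len) {
  margin <- pmin(radius, extent / 4)
  p <- margin + runif(3) * (extent - 2 * margin)
  aniso <- pmin(1, extent / max(extent))
  dir <- .runit() * aniso
  dir <- dir / sqrt(sum(dir^2))
  pts <- matrix(p, ncol = 3)
  laid <- 0
  while (laid < target_len) {
    if (bend_sd > 0) {
      dir <- dir + rnorm(3, 0, bend_sd) * aniso
      dir <- dir / sqrt(sum(dir^2))
    }
    q <- p + step * dir
    for (a in 1:3) {   # reflect at the faces
      while (q[a] < 0 || q[a] > extent[a]) {
        if (q[a] < 0) { q[a] <- -q[a]; dir[a] <- -dir[a] }
        if (q[a] > extent[a]) { q[a] <- 2 * extent[a] - q[a]; dir[a] <- -dir[a] }
      }
    }
    pts <- rbind(pts, q)
    laid <- laid + sqrt(sum((q - p)^2))
    p <- q
  }
  pts
}

.polyline_length <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# separable 3D Gaussian blur, sigma per axis in voxels
.gaussian_blur3 <- function(x, sigma_vox) {
  d <- dim(x)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-((-half):half)^2 / (2 * s^2))
    k <- k / sum(k)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    y <- aperm(x, perm)
    y <- .convolve_dim1(as.numeric(y), dim(y), k)
    x <- aperm(array(y, dim(aperm(x, perm))), order(perm))
  }
  array(x, d)
}

#' Generate a synthetic two-channel axon/cluster volume with ground truth
#'
#' Renders the scene described by a [volume_spec()]: the axon channel is
#' the union of tubes of the stated radius around random-walk centerlines;
#' the cluster channel is a set of non-touching ellipsoids of the requested
#' volumes, placed along axons (at rate `cluster_rate_inside` per um) and
#' in the surrounding volume (Poisson at `cluster_rate_outside` per um^3).
#' Ground truth describes the scene before blur and noise.
#'
#' @param spec a [volume_spec()].
#' @param centerlines optional list of explicit centerline polylines
#'   (matrices with columns z, y, x in um), overriding the random walk;
#'   used for controlled-geometry testing.
#' @return A list with `volume` (an [image_volume()] with channels `axon`
#'   and `cluster`) and `truth` (centerlines, true axon length/mask/volume
#'   fraction, per-cluster table with rendered voxel volumes and
#'   inside/outside labels).
#' @export
generate_volume <- function(spec, centerlines = NULL) {
  stopifnot(inherits(spec, "volume_spec"))
  set.seed(spec$seed)
  d <- spec$shape_voxels
  vs <- spec$voxel_size_um
  extent <- d * vs
  voxvol <- prod(vs)

  if (is.null(centerlines)) {
    centerlines <- lapply(seq_len(spec$n_axons), function(i)
      .walk_centerline(extent, spec$axon_step_um, spec$axon_bend_sd_rad,
                       spec$axon_radius_um, spec$axon_length_um))
  } else {
    centerlines <- lapply(centerlines, function(p) {
      p <- as.matrix(p)
      stopifnot(ncol(p) == 3L)
      p
    })
  }
  axon_mask <- array(FALSE, d)
  for (p in centerlines)
    axon_mask <- .render_tube(axon_mask, vs, p, spec$axon_radius_um)
  lengths <- vapply(centerlines, .polyline_length, numeric(1))
  total_len <- sum(lengths)

  # cluster placement -------------------------------------------------------
  clusters <- list()
  cluster_mask <- array(FALSE, d)
  draw_semi_axes <- function(vol) {
    f <- runif(3, 0.75, 1.35)
    s <- (3 * vol / (4 * pi * prod(f)))^(1/3)
    f * s
  }
  min_sep_ok <- function(centre, semi) {
    for (cl in clusters) {
      if (sqrt(sum((centre - cl$centroid_um)^2)) <
          (max(semi) + cl$max_semi_axis + 2 * max(vs))) return(FALSE)
    }
    TRUE
  }
  overlap_with_axon <- function(centre, semi) {
    tmp <- .render_ellipsoid(array(FALSE, d), vs, centre, semi)
    if (tmp$count == 0L) return(list(frac = NA_real_, mask = NULL, count = 0L))
    vox <- which(tmp$mask)
    list(frac = mean(axon_mask[vox]), mask = tmp$mask, count = tmp$count)
  }
  # A rendering that 26-touches an existing cluster would merge with it into
  # a single connected component, making the planted count unobservable by
  # construction; every placement stage therefore rejects touching renders.
  touches_existing <- function(new_mask) {
    if (length(clusters) == 0L) return(FALSE)
    idx <- which(new_mask)
    zz <- ((idx - 1L) %% d[1]) + 1L
    yy <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
    xx <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      z2 <- pmin(pmax(zz + dz, 1L), d[1])
      y2 <- pmin(pmax(yy + dy, 1L), d[2])
      x2 <- pmin(pmax(xx + dx, 1L), d[3])
      if (any(cluster_mask[cbind(z2, y2, x2)])) return(TRUE)
    }
    FALSE
  }
  # Discretizing a small ellipsoid can retain almost none of its volume
  # (down to a single voxel); such a render misrepresents the planted
  # object, so require the rendered volume to stay within a factor of two
  # of the requested volume.
  render_faithful <- function(count, semi) {
    req <- 4 / 3 * pi * prod(semi)
    v <- count * voxvol
    v >= 0.5 * req && v <= 2 * req
  }
  add_cluster <- function(centre, semi, inside) {
    ov <- overlap_with_axon(centre, semi)
    if (ov$count == 0L) return(FALSE)
    if (!render_faithful(ov$count, semi)) return(FALSE)
    if (touches_existing(ov$mask)) return(FALSE)
    if (inside && ov$frac <= 0.5) return(FALSE)
    if (!inside && ov$frac > 0.05) return(FALSE)
    cluster_mask <<- cluster_mask | ov$mask
    clusters[[length(clusters) + 1L]] <<- list(
      centroid_um = centre, requested_volume_um3 = 4 / 3 * pi * prod(semi),
      volume_um3 = ov$count * voxvol, voxels = ov$count,
      inside_axon = inside, axon_overlap = ov$frac, max_semi_axis = max(semi))
    TRUE
  }
  sample_on_centerline <- function() {
    ax <- sample.int(length(centerlines), 1L, prob = lengths / total_len)
    p <- centerlines[[ax]]
    seg_len <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    s <- runif(1, 0, sum(seg_len))
    cs <- cumsum(seg_len)
    k <- which(cs >= s)[1]
    t0 <- (s - c(0, cs)[k]) / seg_len[k]
    p[k, ] + t0 * (p[k + 1L, ] - p[k, ])
  }
  # The Poisson draw is the truth count: placement constraints (separation,
  # overlap targets) are relaxed progressively rather than dropping clusters.
  place_one <- function(propose, inside) {
    for (try in 1:60) {   # strict: separated and overlap-consistent
      cs <- propose()
      if (min_sep_ok(cs$centre, cs$semi) && add_cluster(cs$centre, cs$semi, inside))
        return(invisible())
    }
    for (try in 1:60) {   # relaxed: overlap-consistent only
      cs <- propose()
      if (add_cluster(cs$centre, cs$semi, inside)) return(invisible())
    }
    for (try in 1:200) {  # last resort: any non-empty, non-touching rendering
      cs <- propose()
      ov <- overlap_with_axon(cs$centre, cs$semi)
      if (ov$count > 0L && render_faithful(ov$count, cs$semi) &&
          !touches_existing(ov$mask)) {
        cluster_mask <<- cluster_mask | ov$mask
        clusters[[length(clusters) + 1L]] <<- list(
          centroid_um = cs$centre,
          requested_volume_um3 = 4 / 3 * pi * prod(cs$semi),
          volume_um3 = ov$count * voxvol, voxels = ov$count,
          inside_axon = inside, axon_overlap = ov$frac,
          max_semi_axis = max(cs$semi))
        return(invisible())
      }
    }
    stop(paste("could not place a separated cluster; reduce cluster rates",
               "or volumes relative to the volume extent"), call. = FALSE)
  }
  draw_vol <- function(range) runif(1, range[1], range[2])
  if (total_len > 0 && spec$cluster_rate_inside > 0) {
    n_in <- rpois(1, spec$cluster_rate_inside * total_len)
    for (i in seq_len(n_in)) {
      place_one(function() {
        centre <- sample_on_centerline() + runif(3, -1, 1) * spec$axon_radius_um / 4
        list(centre = centre,
             semi = draw_semi_axes(draw_vol(spec$cluster_volume_range_um3)))
      }, inside = TRUE)
    }
  }
  if (spec$cluster_rate_outside > 0) {
    vol_out <- (prod(d) - sum(axon_mask)) * voxvol
    n_out <- rpois(1, spec$cluster_rate_outside * vol_out)
    for (i in seq_len(n_out)) {
      place_one(function() {
        list(centre = runif(3) * extent,
             semi = draw_semi_axes(draw_vol(spec$cluster_volume_range_outside_um3)))
      }, inside = FALSE)
    }
  }

  # degrade ----------------------------------------------------------------
  sigma_vox <- spec$psf_sigma_um / vs
  ch_axon <- array(as.numeric(axon_mask), d)
  ch_clus <- array(as.numeric(cluster_mask), d)
  if (any(sigma_vox > 0)) {
    ch_axon <- .gaussian_blur3(ch_axon, sigma_vox)
    ch_clus <- .gaussian_blur3(ch_clus, sigma_vox)
  }
  if (spec$noise_sd > 0) {
    ch_axon <- ch_axon + array(rnorm(prod(d), 0, spec$noise_sd), d)
    ch_clus <- ch_clus + array(rnorm(prod(d), 0, spec$noise_sd), d)
  }

  cluster_table <- if (length(clusters)) {
    data.frame(
      z_um = vapply(clusters, function(c) c$centroid_um[1], 1),
      y_um = vapply(clusters, function(c) c$centroid_um[2], 1),
      x_um = vapply(clusters, function(c) c$centroid_um[3], 1),
      volume_um3 = vapply(clusters, function(c) c$volume_um3, 1),
      requested_volume_um3 = vapply(clusters, function(c) c$requested_volume_um3, 1),
      inside_axon = vapply(clusters, function(c) c$inside_axon, TRUE),
      axon_overlap = vapply(clusters, function(c) c$axon_overlap, 1)
    )
  } else {
    data.frame(z_um = numeric(0), y_um = numeric(0), x_um = numeric(0),
               volume_um3 = numeric(0), requested_volume_um3 = numeric(0),
               inside_axon = logical(0), axon_overlap = numeric(0))
  }

  list(
    volume = image_volume(list(axon = ch_axon, cluster = ch_clus), vs),
    truth = list(
      axon_centerlines = centerlines,
      true_axon_length_um = total_len,
      true_axon_mask = axon_mask,
      true_cluster_mask = cluster_mask,
      true_th_volume_fraction = mean(axon_mask),
      clusters = cluster_table
    )
  )
}
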