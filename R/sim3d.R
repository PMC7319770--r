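#' Otsu threshold of an image channel
#'
#' Computes the threshold that maximizes between-class variance over a
#' 256-bin histogram of the channel's observed intensity range (intensities
#' are not rescaled first). Ties are broken toward the lower threshold.
#'
#' @param channel numeric array (any dimensionality) with >= 2 distinct
#'   values.
#' @param levels number of histogram bins (default 256).
#' @return A list with `threshold` (intensity value) and `mask`
#'   (`channel > threshold`, same shape).
#' @export
otsu_threshold <- function(channel, levels = 256L) {
  v <- as.numeric(channel)
  rng <- range(v)
  if (!is.finite(rng[1]) || !is.finite(rng[2]) || rng[1] == rng[2])
    stop("channel is constant: Otsu threshold undefined", call. = FALSE)
  width <- diff(rng) / levels
  bin <- pmin(levels, floor((v - rng[1]) / width) + 1L)
  counts <- tabulate(bin, nbins = levels)
  mids <- rng[1] + (seq_len(levels) - 0.5) * width
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  n <- w[levels]
  mu_t <- m[levels] / n
  # between-class variance for a cut after bin k (k = 1 .. levels-1)
  k <- seq_len(levels - 1L)
  w0 <- w[k] / n
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, levels - 1L)
  mu0 <- m[k][valid] / w[k][valid]
  sigma_b[valid] <- w0[valid] / (1 - w0[valid]) * (mu0 - mu_t)^2
  kbest <- which.max(sigma_b)
  thr <- rng[1] + kbest * width
  mask <- array(channel > thr, dim = if (is.null(dim(channel))) length(channel) else dim(channel))
  list(threshold = thr, mask = mask)
}

#' Labeled connected components of a voxel mask
#'
#' Labels maximal connected components of a logical 3D mask (a 2D mask is
#' treated as a single-slice volume) and attaches physical volumes.
#'
#' @param mask logical 3D (or 2D) array.
#' @param voxel_size_um `(z, y, x)` voxel size (for 2D input use
#'   `(1, y, x)`).
#' @param connectivity 6, 18 or 26 (26 default; equivalent to 8 in 2D).
#' @return An object of class `"object_set"`: a list of objects, each with
#'   `label`, `voxels` (n x 3 integer matrix of z, y, x indices), `indices`
#'   (linear indices), `n_voxels`, `volume_um3` and `centroid_um`, plus the
#'   grid dimensions and voxel size.
#' @export
label_components <- function(mask, voxel_size_um, connectivity = 26L) {
  if (is.null(dim(mask))) stop("`mask` must be an array", call. = FALSE)
  d <- dim(mask)
  if (length(d) == 2L) {
    dim(mask) <- c(1L, d)
    d <- dim(mask)
  }
  stopifnot(length(d) == 3L, is.logical(mask))
  voxel_size_um <- rep_len(as.numeric(voxel_size_um), 3L)
  labels <- .cc_label(as.logical(mask), as.integer(d), as.integer(connectivity))
  voxvol <- prod(voxel_size_um)
  nz <- d[1]; ny <- d[2]
  idx_all <- which(labels > 0L)
  objs <- list()
  if (length(idx_all)) {
    grp <- split(idx_all, labels[idx_all])
    objs <- lapply(names(grp), function(g) {
      idx <- grp[[g]]
      i0 <- idx - 1L
      z <- i0 %% nz
      y <- (i0 %/% nz) %% ny
      x <- i0 %/% (nz * ny)
      vox <- cbind(z = z + 1L, y = y + 1L, x = x + 1L)
      list(label = as.integer(g), voxels = vox, indices = idx,
           n_voxels = length(idx), volume_um3 = length(idx) * voxvol,
           centroid_um = c(mean(z) * voxel_size_um[1],
                           mean(y) * voxel_size_um[2],
                           mean(x) * voxel_size_um[3]))
    })
  }
  structure(list(objects = objs, dim = d, voxel_size_um = voxel_size_um,
                 connectivity = as.integer(connectivity)),
            class = "object_set")
}

#' @export
print.object_set <- function(x, ...) {
  cat(sprintf("<object_set> %d objects, grid %s, connectivity %d\n",
              length(x$objects), paste(x$dim, collapse = "x"), x$connectivity))
  invisible(x)
}

#' Filter objects by physical volume
#'
#' Retains objects whose volume lies within inclusive bounds. The standard
#' bounds are 0.04-20 um^3 for TH axon components and 0.003-0.04 um^3 for
#' Bassoon clusters.
#'
#' @param objects an [label_components()] result.
#' @param min_um3,max_um3 inclusive volume bounds, `min < max`.
#' @return The filtered `object_set`.
#' @export
size_filter <- function(objects, min_um3, max_um3) {
  stopifnot(inherits(objects, "object_set"))
  if (!(min_um3 < max_um3)) stop("`min_um3` must be < `max_um3`", call. = FALSE)
  keep <- vapply(objects$objects, function(o)
    o$volume_um3 >= min_um3 && o$volume_um3 <= max_um3, TRUE)
  objects$objects <- objects$objects[keep]
  objects
}

#' Rebuild a logical mask from an object set
#' @param objects an `object_set`.
#' @return Logical array of the set's grid dimensions.
#' @export
object_mask <- function(objects) {
  stopifnot(inherits(objects, "object_set"))
  m <- array(FALSE, objects$dim)
  for (o in objects$objects) m[o$indices] <- TRUE
  m
}

#' Volume fraction occupied by a mask
#'
#' Fraction of the region's physical volume covered by TRUE voxels:
#' (mask voxels x voxel volume) / region volume.
#'
#' @param mask logical 3D array.
#' @return Fraction in `[0, 1]`.
#' @export
th_volume_fraction <- function(mask) {
  if (length(mask) == 0L) stop("empty region has zero volume", call. = FALSE)
  mean(mask)
}

#' Skeletonize an axon mask and measure its length
#'
#' Gaussian-smooths the binary mask, re-binarizes at 0.5 and thins it to a
#' one-voxel-wide medial skeleton with a homotopic (26, 6) thinning
#' algorithm. Length is accumulated over the physical-distance
#' (anisotropy-aware) minimum spanning forest of the skeleton's
#' 26-adjacency graph, so staircase configurations are not double-counted.
#'
#' @param mask logical 3D array (axon/TH mask).
#' @param voxel_size_um `(z, y, x)` voxel size.
#' @param gaussian_sigma_um `(z, y, x)` smoothing SDs; defaults to one
#'   voxel per axis.
#' @param region_volume_um3 physical volume used for the length density;
#'   defaults to the full grid volume.
#' @return A list with `skeleton` (logical array), `total_length_um` and
#'   `length_density_um_per_um3`.
#' @export
skeletonize_axons <- function(mask, voxel_size_um,
                              gaussian_sigma_um = NULL,
                              region_volume_um3 = NULL) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  voxel_size_um <- rep_len(as.numeric(voxel_size_um), 3L)
  if (is.null(gaussian_sigma_um)) gaussian_sigma_um <- voxel_size_um
  gaussian_sigma_um <- rep_len(as.numeric(gaussian_sigma_um), 3L)
  if (is.null(region_volume_um3))
    region_volume_um3 <- prod(dim(mask)) * prod(voxel_size_um)
  d <- dim(mask)
  empty <- list(skeleton = array(FALSE, d), total_length_um = 0,
                length_density_um_per_um3 = 0)
  if (!any(mask)) return(empty)
  sm <- array(as.numeric(mask), d)
  sigma_vox <- gaussian_sigma_um / voxel_size_um
  if (any(sigma_vox > 0)) sm <- .gaussian_blur3(sm, sigma_vox)
  bin <- sm > 0.5
  if (!any(bin)) return(empty)
  skel <- .thin3d(as.logical(bin), as.integer(d))
  skel <- array(skel, d)
  idx <- which(skel)
  if (length(idx) < 2L) {
    return(list(skeleton = skel, total_length_um = 0,
                length_density_um_per_um3 = 0))
  }
  nz <- d[1]; ny <- d[2]
  i0 <- idx - 1L
  z <- i0 %% nz; y <- (i0 %/% nz) %% ny; x <- i0 %/% (nz * ny)
  # 26-adjacency edges (each unordered pair once) with physical weights
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  offs <- offs[order(offs$dx, offs$dy, offs$dz), ]
  offs <- offs[1:(nrow(offs) %/% 2), ]  # half-space: each pair once
  from <- to <- integer(0); wt <- numeric(0)
  ord <- order(idx)
  sorted_idx <- idx[ord]
  pos_of <- ord  # sorted_idx[i] is voxel pos_of[i]
  for (r in seq_len(nrow(offs))) {
    zz <- z + offs$dz[r]; yy <- y + offs$dy[r]; xx <- x + offs$dx[r]
    ok <- zz >= 0 & zz < nz & yy >= 0 & yy < ny & xx >= 0 & xx < d[3]
    nbr <- zz[ok] + nz * (yy[ok] + ny * xx[ok]) + 1L
    hit <- match(nbr, sorted_idx)
    src <- which(ok)[!is.na(hit)]
    dst <- pos_of[hit[!is.na(hit)]]
    if (length(src)) {
      from <- c(from, src); to <- c(to, dst)
      wt <- c(wt, rep(sqrt(sum((c(offs$dz[r], offs$dy[r], offs$dx[r]) *
                                  voxel_size_um)^2)), length(src)))
    }
  }
  total <- 0
  if (length(from)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = from, to = to, weight = wt),
      directed = FALSE,
      vertices = data.frame(name = seq_along(idx)))
    mst <- igraph::mst(g, weights = igraph::E(g)$weight)
    total <- sum(igraph::E(mst)$weight)
  }
  list(skeleton = skel, total_length_um = total,
       length_density_um_per_um3 = total / region_volume_um3)
}

#' Overlap fraction of an object with a mask
#'
#' Fraction of the object's voxels that fall inside the mask.
#'
#' @param object one element of an `object_set` (with `indices`).
#' @param mask logical array on the same grid.
#' @return Fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(object, mask) {
  if (is.null(object$indices) || length(object$indices) == 0L)
    stop("empty object has no overlap fraction", call. = FALSE)
  mean(mask[object$indices])
}

#' Classify clusters as inside or outside axons
#'
#' A cluster with strictly more than `threshold` (default 40%) of its
#' voxels inside the axon mask counts as a positive association
#' (in-axon).
#'
#' @param objects an `object_set` of candidate clusters.
#' @param th_mask logical axon mask on the same grid.
#' @param threshold overlap threshold in `(0, 1)`; strict inequality.
#' @return A list with `in_axon` and `out_axon` object sets and the
#'   per-object `overlap` fractions.
#' @export
classify_in_axon <- function(objects, th_mask, threshold = 0.40) {
  stopifnot(inherits(objects, "object_set"),
            threshold > 0, threshold < 1)
  ov <- vapply(objects$objects, overlap_fraction, numeric(1), mask = th_mask)
  inside <- ov > threshold
  in_set <- objects; in_set$objects <- objects$objects[inside]
  out_set <- objects; out_set$objects <- objects$objects[!inside]
  list(in_axon = in_set, out_axon = out_set, overlap = ov)
}

#' Density and mean volume of a cluster set
#'
#' @param objects an `object_set` (typically the in-axon clusters).
#' @param region_volume_um3 normalizing physical volume (ROI volume by
#'   default in [analyze_roi()]; a TH-volume normalizer can be passed
#'   instead).
#' @return A list with `density_per_um3` and `mean_volume_um3` (`NA` for an
#'   empty set).
#' @export
cluster_metrics <- function(objects, region_volume_um3) {
  stopifnot(inherits(objects, "object_set"))
  assert_scalar_num(region_volume_um3, "region_volume_um3")
  if (region_volume_um3 <= 0) stop("region volume must be > 0", call. = FALSE)
  n <- length(objects$objects)
  vols <- vapply(objects$objects, function(o) o$volume_um3, numeric(1))
  list(density_per_um3 = n / region_volume_um3,
       mean_volume_um3 = if (n > 0) mean(vols) else NA_real_)
}

#' Local-shuffle null for cluster/axon association
#'
#' Per round, each object's voxel set is rigidly translated by a
#' displacement drawn uniformly from a box (default 1 x 1 x 1 um^3)
#' centered on its original centroid; displacements that would push the
#' object outside the volume are redrawn. In-axon classification and
#' cluster metrics are recomputed per round (1000 rounds standard) and the
#' actual density and volume are compared to the mean of the shuffled
#' controls.
#'
#' @param objects an `object_set` of clusters.
#' @param th_mask logical axon mask on the same grid.
#' @param region_volume_um3 normalizing volume for densities.
#' @param box_um `(z, y, x)` shuffle box edge lengths, um.
#' @param rounds number of shuffle rounds (default 1000).
#' @param threshold in-axon overlap threshold (default 0.40, strict).
#' @param seed integer seed for the shuffle random stream.
#' @return A list of class `"shuffle_result"`: per-round counts, densities
#'   and mean volumes, their means, and the parameters used.
#' @export
shuffle_null <- function(objects, th_mask, region_volume_um3,
                         box_um = c(1, 1, 1), rounds = 1000L,
                         threshold = 0.40, seed = 1L) {
  stopifnot(inherits(objects, "object_set"), rounds >= 1L)
  box_um <- rep_len(as.numeric(box_um), 3L)
  vs <- objects$voxel_size_um
  d <- objects$dim
  if (any(box_um < vs))
    stop("shuffle box must span at least one voxel per axis", call. = FALSE)
  set.seed(as.integer(seed))
  n_obj <- length(objects$objects)
  counts <- matrix(0L, nrow = rounds, ncol = max(1L, n_obj))
  in_axon <- matrix(FALSE, nrow = rounds, ncol = max(1L, n_obj))
  vol_mat <- matrix(NA_real_, nrow = rounds, ncol = max(1L, n_obj))
  nz <- d[1]; ny <- d[2]
  half_vox <- box_um / 2 / vs   # half box in voxels per axis
  for (j in seq_len(n_obj)) {
    o <- objects$objects[[j]]
    vox <- o$voxels
    bb_lo <- apply(vox, 2, min)
    bb_hi <- apply(vox, 2, max)
    if (any(bb_hi - bb_lo + 1L > d))
      stop("object larger than the volume cannot be shuffled", call. = FALSE)
    # admissible integer offsets keep the bounding box inside the grid
    lo_lim <- 1L - bb_lo
    hi_lim <- d - bb_hi
    draw <- function(n) {
      cbind(round(runif(n, -half_vox[1], half_vox[1])),
            round(runif(n, -half_vox[2], half_vox[2])),
            round(runif(n, -half_vox[3], half_vox[3])))
    }
    offs <- draw(rounds)
    bad <- which(offs[, 1] < lo_lim[1] | offs[, 1] > hi_lim[1] |
                 offs[, 2] < lo_lim[2] | offs[, 2] > hi_lim[2] |
                 offs[, 3] < lo_lim[3] | offs[, 3] > hi_lim[3])
    guard <- 0L
    while (length(bad)) {
      guard <- guard + 1L
      if (guard > 10000L)
        stop("cannot place object inside the volume under the shuffle box",
             call. = FALSE)
      offs[bad, ] <- draw(length(bad))
      bad <- bad[offs[bad, 1] < lo_lim[1] | offs[bad, 1] > hi_lim[1] |
                 offs[bad, 2] < lo_lim[2] | offs[bad, 2] > hi_lim[2] |
                 offs[bad, 3] < lo_lim[3] | offs[bad, 3] > hi_lim[3]]
    }
    # linear-index shift per round (valid: bounding box stays inside)
    dlin <- offs[, 1] + nz * offs[, 2] + nz * ny * offs[, 3]
    shifted <- outer(o$indices, dlin, `+`)  # n_vox x rounds
    ov <- colMeans(matrix(th_mask[shifted], nrow = nrow(vox)))
    in_axon[, j] <- ov > threshold
    vol_mat[, j] <- o$volume_um3
  }
  per_round_count <- if (n_obj > 0) rowSums(in_axon) else rep(0L, rounds)
  per_round_density <- per_round_count / region_volume_um3
  per_round_volume <- rep(NA_real_, rounds)
  if (n_obj > 0) {
    for (r in seq_len(rounds)) {
      sel <- in_axon[r, ]
      if (any(sel)) per_round_volume[r] <- mean(vol_mat[r, sel])
    }
  }
  structure(list(
    rounds = rounds, box_um = box_um, seed = as.integer(seed),
    per_round_in_axon_count = per_round_count,
    per_round_density = per_round_density,
    per_round_mean_volume = per_round_volume,
    mean_shuffled_density = mean(per_round_density),
    mean_shuffled_volume = mean(per_round_volume, na.rm = TRUE),
    in_axon_fraction = if (n_obj > 0) mean(in_axon) else NA_real_
  ), class = "shuffle_result")
}

#' Crop an image volume to a region of interest
#'
#' ROIs are axis-aligned voxel boxes; standard analysis ROIs span
#' 20 x 20 x 2.5 um^3 to 25 x 25 x 2.5 um^3.
#'
#' @param volume an [image_volume()].
#' @param zlim,ylim,xlim inclusive `(first, last)` voxel index ranges.
#' @return The cropped [image_volume()].
#' @export
crop_volume <- function(volume, zlim, ylim, xlim) {
  stopifnot(inherits(volume, "image_volume"))
  d <- dim(volume$channels[[1]])
  for (lim in list(zlim, ylim, xlim))
    if (length(lim) != 2L || lim[1] < 1L || lim[1] > lim[2])
      stop("ROI limits must be ordered voxel ranges", call. = FALSE)
  if (zlim[2] > d[1] || ylim[2] > d[2] || xlim[2] > d[3])
    stop("ROI exceeds the volume", call. = FALSE)
  chans <- lapply(volume$channels, function(ch)
    ch[zlim[1]:zlim[2], ylim[1]:ylim[2], xlim[1]:xlim[2], drop = FALSE])
  image_volume(chans, volume$voxel_size_um)
}

#' Default analysis configuration for 3D volumes
#'
#' @param th_size_um3 TH component volume bounds (default 0.04-20 um^3).
#' @param cluster_size_um3 cluster volume bounds (default 0.003-0.04 um^3).
#' @param overlap_threshold in-axon overlap threshold (default 0.40).
#' @param connectivity component connectivity (default 26).
#' @param skeleton_sigma_um Gaussian smoothing before thinning; `NULL`
#'   means one voxel per axis.
#' @param shuffle_rounds local-shuffle rounds (default 1000).
#' @param shuffle_box_um shuffle box, um (default 1 x 1 x 1).
#' @param density_normalizer `"roi"` (per ROI volume, default) or `"th"`
#'   (per TH volume).
#' @param seed random seed for the shuffle stream.
#' @return A named list of parameters for [analyze_roi()].
#' @export
sim3d_config <- function(th_size_um3 = c(0.04, 20),
                         cluster_size_um3 = c(0.003, 0.04),
                         overlap_threshold = 0.40,
                         connectivity = 26L,
                         skeleton_sigma_um = NULL,
                         shuffle_rounds = 1000L,
                         shuffle_box_um = c(1, 1, 1),
                         density_normalizer = c("roi", "th"),
                         seed = 1L) {
  list(th_size_um3 = th_size_um3, cluster_size_um3 = cluster_size_um3,
       overlap_threshold = overlap_threshold,
       connectivity = as.integer(connectivity),
       skeleton_sigma_um = skeleton_sigma_um,
       shuffle_rounds = as.integer(shuffle_rounds),
       shuffle_box_um = shuffle_box_um,
       density_normalizer = match.arg(density_normalizer),
       seed = as.integer(seed))
}

#' Full per-ROI quantification of an axon/cluster volume
#'
#' Runs the complete pipeline on one ROI: Otsu thresholding of both
#' channels, connected components, size filtering (TH 0.04-20 um^3,
#' clusters 0.003-0.04 um^3), TH volume fraction, skeleton-based axon
#' length density, in-axon cluster classification (> 40% overlap with the
#' size-filtered TH mask), cluster density and mean volume, and the
#' local-shuffle null.
#'
#' @param volume an [image_volume()] with channels named `axon` and
#'   `cluster` (already cropped to the ROI, or use [crop_volume()]).
#' @param config a [sim3d_config()].
#' @return A list with `metrics` (th_volume_fraction, axon_length_density,
#'   in_axon_cluster_density, in_axon_mean_cluster_volume,
#'   shuffled_density, shuffled_volume), the intermediate object sets and
#'   the shuffle result.
#' @export
analyze_roi <- function(volume, config = sim3d_config()) {
  stopifnot(inherits(volume, "image_volume"))
  if (!all(c("axon", "cluster") %in% names(volume$channels)))
    stop("volume must have channels named 'axon' and 'cluster'", call. = FALSE)
  vs <- volume$voxel_size_um
  d <- dim(volume$channels$axon)
  roi_vol <- prod(d) * prod(vs)

  th_seg <- otsu_threshold(volume$channels$axon)
  cl_seg <- otsu_threshold(volume$channels$cluster)

  th_obj <- label_components(th_seg$mask, vs, config$connectivity)
  th_obj <- size_filter(th_obj, config$th_size_um3[1], config$th_size_um3[2])
  th_mask <- object_mask(th_obj)

  cl_obj <- label_components(cl_seg$mask, vs, config$connectivity)
  cl_obj <- size_filter(cl_obj, config$cluster_size_um3[1],
                        config$cluster_size_um3[2])

  frac <- th_volume_fraction(th_mask)
  skel <- skeletonize_axons(th_mask, vs,
                            gaussian_sigma_um = config$skeleton_sigma_um,
                            region_volume_um3 = roi_vol)

  cls <- classify_in_axon(cl_obj, th_mask, config$overlap_threshold)
  norm_vol <- if (config$density_normalizer == "th")
    sum(th_mask) * prod(vs) else roi_vol
  if (norm_vol <= 0) norm_vol <- roi_vol
  met <- cluster_metrics(cls$in_axon, norm_vol)

  shuf <- NULL
  shuffled_density <- NA_real_
  shuffled_volume <- NA_real_
  if (length(cl_obj$objects) > 0 && config$shuffle_rounds > 0) {
    shuf <- shuffle_null(cl_obj, th_mask, norm_vol,
                         box_um = config$shuffle_box_um,
                         rounds = config$shuffle_rounds,
                         threshold = config$overlap_threshold,
                         seed = config$seed)
    shuffled_density <- shuf$mean_shuffled_density
    shuffled_volume <- shuf$mean_shuffled_volume
  }
  list(
    metrics = list(
      th_volume_fraction = frac,
      axon_length_density = skel$length_density_um_per_um3,
      in_axon_cluster_density = met$density_per_um3,
      in_axon_mean_cluster_volume = met$mean_volume_um3,
      shuffled_density = shuffled_density,
      shuffled_volume = shuffled_volume
    ),
    thresholds = list(axon = th_seg$threshold, cluster = cl_seg$threshold),
    th_objects = th_obj, cluster_objects = cl_obj,
    classification = cls, skeleton = skel, shuffle = shuf,
    roi_volume_um3 = roi_vol
  )
}
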