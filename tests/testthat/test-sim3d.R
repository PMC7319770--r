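test_that("otsu_threshold separates a clear bimodal mixture", {
  set.seed(1)
  v <- c(rnorm(5000, 0.1, 0.02), rnorm(1500, 0.9, 0.05))
  seg <- otsu_threshold(array(v, c(10, 10, 65)))
  # the cut must fall in the gap: all background below, all signal above
  expect_gte(seg$threshold, max(v[1:5000]))
  expect_lt(seg$threshold, min(v[5001:6500]))
  expect_equal(sum(seg$mask), 1500)
  expect_error(otsu_threshold(array(1, c(2, 2, 2))), "constant")
})

test_that("otsu_threshold matches the exhaustive oracle on assorted data", {
  set.seed(2)
  for (i in 1:5) {
    v <- c(rlnorm(2000, -2, 0.4), rnorm(500, 2, 0.3))
    got <- otsu_threshold(v)$threshold
    want <- oracle_otsu(v)$threshold
    expect_equal(got, want)
  }
})

test_that("label_components agrees with a flood-fill oracle", {
  set.seed(3)
  for (conn in c(6L, 18L, 26L)) {
    mask <- array(runif(6 * 7 * 8) < 0.3, c(6, 7, 8))
    got <- label_components(mask, c(1, 1, 1), conn)
    want <- oracle_components(mask, conn)
    expect_equal(length(got$objects), length(want))
    got_sets <- lapply(got$objects, function(o) sort(o$indices))
    got_sets <- got_sets[order(vapply(got_sets, min, 1L))]
    expect_equal(got_sets, want)
  }
})

test_that("label_components reports physical volumes and centroids", {
  mask <- array(FALSE, c(4, 4, 4))
  mask[2, 2:3, 2] <- TRUE
  obj <- label_components(mask, c(0.125, 0.04, 0.04), 26L)
  expect_length(obj$objects, 1)
  o <- obj$objects[[1]]
  expect_equal(o$n_voxels, 2L)
  expect_equal(o$volume_um3, 2 * 0.125 * 0.04 * 0.04)
  expect_equal(o$centroid_um, c(1 * 0.125, 1.5 * 0.04, 1 * 0.04))
})

test_that("size_filter bounds are inclusive", {
  mask <- array(FALSE, c(3, 10, 10))
  mask[2, 1:2, 1] <- TRUE      # 2 voxels
  mask[2, 5:8, 5] <- TRUE      # 4 voxels
  obj <- label_components(mask, c(1, 1, 1), 26L)
  expect_length(size_filter(obj, 2, 4)$objects, 2)   # both bounds inclusive
  kept <- size_filter(obj, 3, 4)
  expect_length(kept$objects, 1)
  expect_equal(kept$objects[[1]]$n_voxels, 4L)
  expect_error(size_filter(obj, 3, 2), "min_um3")
})

test_that("object_mask inverts label_components", {
  set.seed(4)
  mask <- array(runif(5 * 6 * 7) < 0.25, c(5, 6, 7))
  obj <- label_components(mask, c(1, 1, 1), 26L)
  expect_identical(object_mask(obj), mask)
})

test_that("th_volume_fraction is the TRUE-voxel fraction", {
  mask <- array(FALSE, c(2, 2, 5))
  mask[1, 1, 1:3] <- TRUE
  expect_equal(th_volume_fraction(mask), 3 / 20)
})

test_that("classification threshold is strict", {
  mask <- array(FALSE, c(1, 1, 10))
  mask[1, 1, 1:4] <- TRUE      # object of 10 voxels, 4 inside -> exactly 0.40
  obj <- list(indices = 1:10)
  expect_equal(overlap_fraction(obj, mask), 0.4)
  objs <- label_components(array(TRUE, c(1, 1, 10)), c(1, 1, 1), 26L)
  cls <- classify_in_axon(objs, mask, threshold = 0.40)
  expect_length(cls$in_axon$objects, 0)   # 0.40 is NOT > 0.40
  expect_length(cls$out_axon$objects, 1)
  cls2 <- classify_in_axon(objs, mask, threshold = 0.39)
  expect_length(cls2$in_axon$objects, 1)
})

test_that("cluster_metrics computes density and mean volume", {
  mask <- array(FALSE, c(2, 4, 4))
  mask[1, 1, 1] <- TRUE
  mask[2, 3:4, 3] <- TRUE
  obj <- label_components(mask, c(1, 1, 1), 6L)
  met <- cluster_metrics(obj, region_volume_um3 = 32)
  expect_equal(met$density_per_um3, 2 / 32)
  expect_equal(met$mean_volume_um3, 1.5)
  empty <- obj; empty$objects <- list()
  expect_true(is.na(cluster_metrics(empty, 32)$mean_volume_um3))
})

test_that("crop_volume extracts the stated voxel box", {
  arr <- array(seq_len(4 * 5 * 6), c(4, 5, 6))
  vol <- image_volume(list(axon = arr), c(1, 1, 1))
  cr <- crop_volume(vol, c(2, 3), c(1, 5), c(4, 6))
  expect_equal(dim(cr$channels$axon), c(2, 5, 3))
  expect_equal(cr$channels$axon, arr[2:3, 1:5, 4:6, drop = FALSE])
  expect_error(crop_volume(vol, c(2, 9), c(1, 5), c(4, 6)), "exceeds")
})

test_that("skeleton length of a straight tube approximates its length", {
  spec <- volume_spec(shape_voxels = c(16L, 40L, 220L),
                      voxel_size_um = c(0.125, 0.05, 0.05),
                      n_axons = 1L, cluster_rate_inside = 0,
                      cluster_rate_outside = 0, seed = 1L)
  line <- rbind(c(1.0, 1.0, 0.5), c(1.0, 1.0, 10.5))   # 10 um along x
  g <- generate_volume(spec, centerlines = list(line))
  sk <- skeletonize_axons(g$truth$true_axon_mask, spec$voxel_size_um)
  expect_equal(sk$total_length_um, 10, tolerance = 0.1)
  expect_equal(sk$length_density_um_per_um3,
               sk$total_length_um / (prod(spec$shape_voxels) *
                                       prod(spec$voxel_size_um)))
})

test_that("skeletonize_axons handles empty and tiny masks", {
  empty <- skeletonize_axons(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  expect_equal(empty$total_length_um, 0)
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  res <- skeletonize_axons(one, c(1, 1, 1), gaussian_sigma_um = c(0, 0, 0))
  expect_equal(res$total_length_um, 0)
})

test_that("shuffle_null keeps an object inside an all-TRUE mask in-axon", {
  mask <- array(TRUE, c(20, 20, 20))
  objm <- array(FALSE, c(20, 20, 20))
  objm[10, 10, 10] <- TRUE
  obj <- label_components(objm, c(0.2, 0.2, 0.2), 26L)
  res <- shuffle_null(obj, mask, region_volume_um3 = 64,
                      box_um = c(1, 1, 1), rounds = 50, seed = 1L)
  expect_equal(res$in_axon_fraction, 1)
  expect_equal(res$mean_shuffled_density, 1 / 64)
})

test_that("shuffle_null is deterministic for a fixed seed", {
  set.seed(99)
  mask <- array(runif(8000) < 0.3, c(20, 20, 20))
  objm <- array(FALSE, c(20, 20, 20))
  objm[c(2105, 4210, 6301)] <- TRUE
  obj <- label_components(objm, c(0.2, 0.2, 0.2), 26L)
  r1 <- shuffle_null(obj, mask, 64, rounds = 30, seed = 5L)
  r2 <- shuffle_null(obj, mask, 64, rounds = 30, seed = 5L)
  expect_identical(r1$per_round_in_axon_count, r2$per_round_in_axon_count)
})

test_that("analyze_roi returns the six headline metrics", {
  spec <- volume_spec(shape_voxels = c(12L, 60L, 60L),
                      voxel_size_um = c(0.125, 0.05, 0.05),
                      n_axons = 1L, cluster_rate_inside = 1,
                      cluster_rate_outside = 0.5,
                      cluster_volume_range_um3 = c(0.008, 0.03), seed = 21L)
  g <- generate_volume(spec)
  res <- analyze_roi(g$volume, sim3d_config(shuffle_rounds = 20L))
  expect_named(res$metrics,
               c("th_volume_fraction", "axon_length_density",
                 "in_axon_cluster_density", "in_axon_mean_cluster_volume",
                 "shuffled_density", "shuffled_volume"))
  expect_gte(res$metrics$th_volume_fraction, 0)
  expect_s3_class(res$shuffle, "shuffle_result")
  bad <- image_volume(list(a = array(0:1, c(2, 2, 2))), c(1, 1, 1))
  expect_error(analyze_roi(bad), "axon")
})
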