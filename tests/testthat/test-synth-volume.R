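test_that("generate_volume is deterministic for a fixed seed", {
  spec <- volume_spec(shape_voxels = c(10L, 50L, 50L),
                      voxel_size_um = c(0.125, 0.05, 0.05),
                      noise_sd = 0.05, psf_sigma_um = c(0.1, 0.05, 0.05),
                      seed = 31L)
  g1 <- generate_volume(spec)
  g2 <- generate_volume(spec)
  expect_identical(g1$volume$channels, g2$volume$channels)
  expect_identical(g1$truth$clusters, g2$truth$clusters)
})

test_that("volume_spec validates its arguments", {
  expect_error(volume_spec(shape_voxels = c(4, 4, 4)), ">= 8")
  expect_error(volume_spec(axon_radius_um = 0.01), "unresolvable")
  expect_error(volume_spec(cluster_volume_range_um3 = c(0.04, 0.003)),
               "ordered")
  expect_error(volume_spec(noise_sd = -0.1), ">= 0")
})

test_that("truth volume fraction matches the rendered axon mask", {
  g <- generate_volume(volume_spec(shape_voxels = c(10L, 60L, 60L),
                                   voxel_size_um = c(0.125, 0.05, 0.05),
                                   cluster_rate_inside = 0,
                                   cluster_rate_outside = 0, seed = 8L))
  expect_equal(g$truth$true_th_volume_fraction, mean(g$truth$true_axon_mask))
  expect_gt(g$truth$true_th_volume_fraction, 0)
})

test_that("explicit centerlines give exact truth length", {
  spec <- volume_spec(shape_voxels = c(14L, 60L, 120L),
                      voxel_size_um = c(0.125, 0.05, 0.05),
                      n_axons = 1L, cluster_rate_inside = 0,
                      cluster_rate_outside = 0, seed = 1L)
  line <- rbind(c(0.8, 1.5, 0.5), c(0.8, 1.5, 4.5))
  g <- generate_volume(spec, centerlines = list(line))
  expect_equal(g$truth$true_axon_length_um, 4)
})

test_that("inside clusters overlap axons, outside clusters do not", {
  spec <- volume_spec(shape_voxels = c(16L, 80L, 80L),
                      voxel_size_um = c(0.125, 0.05, 0.05),
                      cluster_rate_inside = 0.8, cluster_rate_outside = 0.5,
                      cluster_volume_range_um3 = c(0.008, 0.03), seed = 12L)
  g <- generate_volume(spec)
  cl <- g$truth$clusters
  expect_gt(nrow(cl), 0)
  expect_true(all(cl$axon_overlap[cl$inside_axon] > 0.5))
  expect_true(all(cl$axon_overlap[!cl$inside_axon] <= 0.05))
})

test_that("separate outside volume range is honored", {
  spec <- volume_spec(shape_voxels = c(16L, 80L, 80L),
                      voxel_size_um = c(0.125, 0.05, 0.05),
                      cluster_rate_inside = 0.8, cluster_rate_outside = 0.5,
                      cluster_volume_range_um3 = c(0.005, 0.012),
                      cluster_volume_range_outside_um3 = c(0.02, 0.035),
                      seed = 13L)
  g <- generate_volume(spec)
  cl <- g$truth$clusters
  expect_true(all(cl$requested_volume_um3[cl$inside_axon] <= 0.013))
  expect_true(all(cl$requested_volume_um3[!cl$inside_axon] >= 0.019))
})

test_that("random-walk centerlines stay inside the volume extent", {
  spec <- volume_spec(shape_voxels = c(12L, 100L, 100L),
                      voxel_size_um = c(0.125, 0.05, 0.05),
                      n_axons = 3L, cluster_rate_inside = 0,
                      cluster_rate_outside = 0, seed = 17L)
  g <- generate_volume(spec)
  extent <- spec$shape_voxels * spec$voxel_size_um
  for (p in g$truth$axon_centerlines) {
    expect_true(all(p >= 0))
    expect_true(all(sweep(p, 2, extent, `<=`)))
  }
})
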