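test_that("generate_puncta_field is deterministic for a fixed seed", {
  spec <- puncta_field_spec(n_objects = c(10L, 8L, 8L), noise_sd = 0.03,
                            psf_sigma_um = 0.08, seed = 41L)
  g1 <- generate_puncta_field(spec)
  g2 <- generate_puncta_field(spec)
  expect_identical(g1$channels, g2$channels)
  expect_identical(g1$truth, g2$truth)
})

test_that("truth table has the planted counts and categories", {
  g <- generate_puncta_field(puncta_field_spec(
    n_objects = c(bassoon_th = 12L, th_only = 7L, bassoon_only = 5L),
    n_oversize = 2L, n_elongated = 3L, seed = 42L))
  tab <- table(g$truth$category[!g$truth$out_of_range])
  expect_equal(as.integer(tab[c("Bassoon+TH+", "Bassoon-TH+", "Bassoon+TH-")]),
               c(12L, 7L, 5L))
  expect_equal(sum(g$truth$out_of_range), 5L)
})

test_that("in-range planted areas fall inside the detection window", {
  g <- generate_puncta_field(puncta_field_spec(
    n_objects = c(15L, 15L, 15L),
    punctum_area_range_um2 = c(0.25, 0.9), seed = 43L))
  a <- g$truth$area_um2[!g$truth$out_of_range]
  expect_true(all(a >= 0.2 & a <= 1.0))
})

test_that("oversize objects exceed the window; bars are elongated", {
  g <- generate_puncta_field(puncta_field_spec(
    n_objects = c(0L, 0L, 0L), n_oversize = 3L, n_elongated = 0L, seed = 44L))
  expect_true(all(g$truth$area_um2 > 1.0))
  g2 <- generate_puncta_field(puncta_field_spec(
    n_objects = c(0L, 0L, 0L), n_elongated = 3L, seed = 45L))
  expect_true(all(g2$truth$area_um2 >= 0.2 & g2$truth$area_um2 <= 1.0))
})

test_that("channel membership follows the category", {
  g <- generate_puncta_field(puncta_field_spec(
    n_objects = c(0L, 5L, 0L), syt1_positive_fraction = 0, seed = 46L))
  expect_gt(sum(g$channels$th > 0), 0)
  expect_equal(sum(g$channels$bassoon > 0), 0)
  expect_equal(sum(g$channels$syt1 > 0), 0)
})

test_that("spec validation catches bad fractions and counts", {
  expect_error(puncta_field_spec(syt1_positive_fraction = 1.2), "\\[0, 1\\]")
  expect_error(puncta_field_spec(n_objects = c(-1L, 0L, 0L)), ">= 0")
  expect_error(puncta_field_spec(punctum_area_range_um2 = c(1, 0.2)),
               "ordered")
})
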