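test_that("rolling-ball subtraction removes a broad background, keeps puncta", {
  px <- 0.1
  ny <- nx <- 128
  bg <- outer(seq(0, 0.4, length.out = ny), rep(1, nx))  # smooth gradient
  img <- bg
  img[60:64, 60:64] <- img[60:64, 60:64] + 1             # small punctum
  out <- rolling_ball_background(img, px, radius_um = 1)
  expect_lt(max(out[1:40, 1:40]), 0.08)                  # background gone
  expect_gt(max(out[60:64, 60:64]), 0.9)                 # punctum kept
  expect_error(rolling_ball_background(img, px, radius_um = 0.05),
               "smaller than one pixel")
})

test_that("detect_puncta applies size and shape filters", {
  px <- 0.1
  img <- matrix(0, 128, 128)
  img[20:24, 20:24] <- 1      # 25 px = 0.25 um^2, ratio 1 -> kept
  img[60:61, 60:61] <- 1      # 4 px = 0.04 um^2 -> too small
  img[90:109, 90:109] <- 1    # 400 px = 4 um^2 -> too large
  img[40:41, 80:100] <- 1     # 2 x 21 bar -> elongated
  det <- detect_puncta(img, px)
  expect_equal(det$n_raw, 4L)
  expect_length(det$objects, 1)
  expect_equal(det$objects[[1]]$area_um2, 0.25)
  expect_lt(det$objects[[1]]$axis_ratio, 1.5)
})

test_that("categorize_objects pairs channels and scores Syt-1 inclusively", {
  px <- 0.1
  blank <- matrix(0, 64, 64)
  b <- blank; t_ <- blank; s <- blank
  # pair: bassoon and TH fully overlapping
  b[10:14, 10:14] <- 1; t_[10:14, 10:14] <- 1
  # TH-only object with exactly 20% Syt-1 coverage (inclusive boundary):
  # a 5x5 Syt-1 square shares exactly its rightmost column with the TH square
  t_[30:34, 30:34] <- 1
  s[30:34, 26:30] <- 1        # covers 5 of 25 TH pixels = 0.20
  # bassoon-only object with zero Syt-1
  b[50:54, 50:54] <- 1
  db <- detect_puncta(b, px); dt <- detect_puncta(t_, px)
  sset <- detect_puncta(s, px)
  res <- categorize_objects(db, dt, sset)
  expect_equal(sort(res$summary$n),
               sort(c(1L, 1L, 1L)))
  tab <- res$table
  expect_true(tab$syt1_positive[tab$category == "Bassoon-TH+"])   # 0.20 counts
  expect_false(tab$syt1_positive[tab$category == "Bassoon+TH-"])
  expect_equal(tab$syt1_overlap[tab$category == "Bassoon-TH+"], 0.2)
})

test_that("co-positivity below the 20% overlap threshold splits the pair", {
  px <- 0.1
  b <- matrix(0, 64, 64); t_ <- b; s <- b
  t_[10:14, 10:14] <- 1       # 25 px
  b[14:18, 10:14] <- 1        # 25 px, shares one 5-px row: 5/25 = 0.2 -> pair
  db <- detect_puncta(b, px); dt <- detect_puncta(t_, px)
  ds <- detect_puncta(s + 0.001 * matrix(seq_len(64 * 64), 64), px)
  res <- categorize_objects(db, dt, ds)
  expect_equal(res$summary$n[res$summary$category == "Bassoon+TH+"], 1L)
  # shift bassoon one more row: 0 shared pixels -> two singles
  b2 <- matrix(0, 64, 64); b2[16:20, 10:14] <- 1
  res2 <- categorize_objects(detect_puncta(b2, px), dt, ds)
  expect_equal(res2$summary$n[res2$summary$category == "Bassoon+TH+"], 0L)
  expect_equal(res2$summary$n[res2$summary$category == "Bassoon-TH+"], 1L)
  expect_equal(res2$summary$n[res2$summary$category == "Bassoon+TH-"], 1L)
})

test_that("analyze_synaptosomes recovers planted counts on a clean field", {
  g <- generate_puncta_field(puncta_field_spec(
    image_shape_px = c(256L, 256L),
    n_objects = c(bassoon_th = 8L, th_only = 6L, bassoon_only = 5L),
    syt1_positive_fraction = c(1, 0, 1), seed = 51L))
  res <- analyze_synaptosomes(g$channels, g$pixel_size_um)
  s <- res$summary
  expect_equal(s$n[s$category == "Bassoon+TH+"], 8L)
  expect_equal(s$n[s$category == "Bassoon-TH+"], 6L)
  expect_equal(s$n[s$category == "Bassoon+TH-"], 5L)
  expect_equal(s$syt1_positive_fraction[s$category == "Bassoon+TH+"], 1)
  expect_equal(s$syt1_positive_fraction[s$category == "Bassoon-TH+"], 0)
})
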