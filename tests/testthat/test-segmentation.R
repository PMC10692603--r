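test_that("thresholding follows the mask conventions", {
  f <- matrix(200L, 16, 16)
  m <- binarize(f, 110)
  expect_false(any(m$mask))
  f[3:12, 3:12] <- 50L
  m <- binarize(f, 110)
  expect_equal(sum(m$mask), 100)
  # bright-object polarity
  g <- matrix(10L, 8, 8); g[2:3, 2:3] <- 200L
  expect_equal(sum(binarize(g, 110, "bright_objects")$mask), 4)
  expect_error(binarize(f, 300), "\\[0, 255\\]")
  expect_warning(binarize(f, 90), "advisory")
  expect_warning(binarize(matrix(50L, 4, 4), 110), "foreground fraction")
})

test_that("labeling matches the flood-fill oracle on random images", {
  set.seed(42)
  for (i in 1:30) {
    m <- matrix(runif(64 * 64) < 0.35, 64, 64)
    for (conn in c(8, 4)) {
      expect_true(same_labeling(label_mask(m, conn),
                                flood_fill_label(m, conn)),
                  info = paste("image", i, "connectivity", conn))
    }
  }
})

test_that("diagonally touching pixels merge under 8- but not 4-connectivity", {
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(max(label_mask(m, 8)), 1)
  expect_equal(max(label_mask(m, 4)), 2)
})

test_that("spot morphometrics are correct for simple shapes", {
  # two disjoint 3x3 squares
  f <- matrix(200L, 20, 20)
  f[2:4, 2:4] <- 50L; f[10:12, 14:16] <- 50L
  spots <- detect_spots(binarize(f, 110), pixel_size = 2)
  expect_equal(nrow(spots), 2)
  expect_equal(spots$area_um2, c(36, 36)) # 9 px * 4 um^2
  # centroid of the first square: pixel centres (2..4 - 0.5) * 2
  expect_equal(spots$x_um[1], 5)
  expect_equal(spots$y_um[1], 5)

  # rasterized disk R = 10 px
  fd <- frame_with_disk(64, 32, 32, 10)
  sd_ <- detect_spots(binarize(fd, 110), pixel_size = 1)
  expect_equal(sd_$area_um2, 100 * pi, tolerance = 0.02)
  expect_gte(sd_$circularity, 0.9)
  expect_equal(sd_$radius_um, 10, tolerance = 0.05)

  # 5:1 ellipse is clearly elongated
  fe <- frame_with_ellipse(128, 64, 64, a = 50, b = 10)
  se <- detect_spots(binarize(fe, 110), pixel_size = 1)
  expect_lt(se$circularity, 0.5)
})

test_that("equivalent radius recovers disk radii within 5% for R >= 5", {
  for (R in c(5, 8, 12, 20)) {
    f <- frame_with_disk(2 * R + 14, R + 7, R + 7, R)
    s <- detect_spots(binarize(f, 110), pixel_size = 1)
    expect_equal(s$radius_um, R, tolerance = 0.05)
  }
})

test_that("circularity stays in (0, 1] on random blobs", {
  set.seed(7)
  for (i in 1:20) {
    m <- matrix(runif(40 * 40) < 0.3, 40, 40)
    s <- detect_spots(m, pixel_size = 1)
    expect_true(all(s$circularity > 0 & s$circularity <= 1))
  }
})

test_that("area is additive over disjoint tiles of a mask", {
  set.seed(3)
  m <- matrix(runif(60 * 60) < 0.4, 60, 60)
  whole <- sum(detect_spots(m, pixel_size = 1.5)$area_um2)
  tiles <- list(m[1:30, 1:30], m[1:30, 31:60], m[31:60, 1:30],
                m[31:60, 31:60])
  parts <- sum(vapply(tiles, function(t)
    sum(detect_spots(t, pixel_size = 1.5)$area_um2), 0))
  expect_equal(whole, parts)
})

test_that("border components are kept and flagged; empty masks allowed", {
  f <- matrix(200L, 10, 10); f[1:3, 1:3] <- 50L; f[6:7, 6:7] <- 50L
  s <- detect_spots(binarize(f, 110), pixel_size = 1)
  expect_equal(s$on_border, c(TRUE, FALSE))
  expect_equal(nrow(detect_spots(matrix(FALSE, 5, 5), pixel_size = 1)), 0)
  # quality = pixel count; the permissive default keeps single pixels
  f1 <- matrix(200L, 5, 5); f1[3, 3] <- 50L
  expect_equal(detect_spots(binarize(f1, 110), pixel_size = 1)$pixel_count,
               1)
  expect_equal(nrow(detect_spots(binarize(f1, 110), pixel_size = 1,
                                 quality_threshold = 2)), 0)
})

test_that("spot counts are stable across the working threshold band", {
  ss <- scene_small()
  n100 <- nrow(segment_stack(ss$scene$stack, 100, ss$cfg$pixel_size))
  n118 <- nrow(segment_stack(ss$scene$stack, 118, ss$cfg$pixel_size))
  expect_lt(abs(n100 - n118) / n100, 0.05)
})
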