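# Dataset preparation: Otsu thresholding, chroma segmentation, cropping,
# resizing, normalization, sky augmentation and dark-sky filtering.

test_that("otsu_threshold matches hand-constructed bimodal cases", {
  half <- matrix(c(rep(0, 50), rep(255, 50)), 10)
  expect_identical(otsu_threshold(half), 0L)     # ties break low
  two <- matrix(c(rep(10, 50), rep(200, 50)), 10)
  expect_identical(otsu_threshold(two), 10L)
  expect_error(otsu_threshold(matrix(7, 4, 4)), "degenerate")
})

test_that("otsu_threshold agrees with the brute-force variance oracle", {
  set.seed(101)
  for (i in 1:10) {
    ch <- matrix(sample(0:255, 400, replace = TRUE), 20)
    expect_identical(otsu_threshold(ch), as.integer(otsu_brute_force(ch)))
  }
  # and on bimodal mixtures closer to real channels
  for (i in 1:5) {
    ch <- matrix(pmin(pmax(round(c(rnorm(200, 60, 15), rnorm(200, 180, 20))), 0), 255), 20)
    expect_identical(otsu_threshold(ch), as.integer(otsu_brute_force(ch)))
  }
})

test_that("segment_tassel recovers fixture masks and forces black backgrounds", {
  p <- tassel_params(resolution = 64)
  ious <- vapply(1:10, function(s) {
    seg <- segment_tassel(make_lab_scene(p, seed = s))
    mask_iou(seg$mask, make_tassel_mask(p, s))
  }, 0)
  expect_true(all(ious >= 0.9))
  seg <- segment_tassel(make_lab_scene(p, seed = 1))
  bg <- seg$mask == 0
  for (ch in 1:3) expect_true(all(seg$segmented[, , ch][bg] == 0))
  # already-black-background input: segmentation preserves foreground pixels
  img <- make_tassel_image(p, 3)
  seg2 <- segment_tassel(img)
  fg <- seg2$mask == 1
  for (ch in 1:3)
    expect_identical(seg2$segmented[, , ch][fg], img[, , ch][fg])
  blue <- array(rep(c(0, 0, 255), each = 64 * 64), c(64, 64, 3))
  expect_error(segment_tassel(blue), "degenerate")
})

test_that("crop_center takes the centred half-open window", {
  img <- array(0, c(10, 10, 3))
  img[, , 1] <- matrix(1:100, 10, 10)
  cr <- crop_center(img, 4, 4)
  # rows/cols 4..7 in 1-based indexing (offset floor((10-4)/2) = 3)
  expect_identical(cr[, , 1], img[4:7, 4:7, 1])
  expect_identical(crop_center(img, 10, 10), img)
  expect_error(crop_center(img, 11, 4), "crop")
})

test_that("bicubic resize preserves constants and smooth gradients", {
  const <- array(90, c(16, 16, 3))
  expect_true(all(resize_image(const, 32) == 90))
  img <- random_image8(32, 32, 5)
  expect_lte(max(abs(resize_image(img, 32) - img)), 1)
  grad <- array(0, c(128, 128, 3))
  for (ch in 1:3) grad[, , ch] <- matrix(rep(round(seq(0, 255, length.out = 128)), each = 128), 128)
  rt <- resize_image(resize_image(grad, 64), 128)
  expect_lt(mean(abs(rt - grad)), 5)
})

test_that("normalization maps 8-bit to [-1,1] and round-trips exactly", {
  expect_equal(normalize_image(0), -1)
  expect_equal(normalize_image(255), 1)
  expect_equal(normalize_image(127.5), 0)
  levels <- 0:255
  expect_identical(denormalize_image(normalize_image(levels)), as.numeric(levels))
  img <- random_image8(8, 8, 3)
  expect_identical(denormalize_image(normalize_image(img)), img * 1)
})

test_that("augment_sky scales saturation and value, leaving hue alone", {
  gray <- array(120, c(8, 8, 3))
  expect_identical(augment_sky(gray, sat_scale = 0.6), gray)
  px <- array(rep(c(100, 50, 50), each = 64), c(8, 8, 3))   # S = 0.5
  out <- augment_sky(px, sat_scale = 0.6)
  s_out <- unname(rgb2hsv(matrix(out[1, 1, ], 3), maxColorValue = 255)[2, 1])
  expect_equal(s_out, 0.3, tolerance = 0.02)
  out2 <- augment_sky(px, sat_scale = 1, lum_scale = 1.3)
  v_out <- unname(rgb2hsv(matrix(out2[1, 1, ], 3), maxColorValue = 255)[3, 1])
  expect_equal(v_out, (100 / 255) * 1.3, tolerance = 0.02)
  hue <- function(img) rgb2hsv(matrix(img[1, 1, ], 3), maxColorValue = 255)[1, 1]
  expect_equal(hue(augment_sky(px, 0.6)), hue(px), tolerance = 0.02)
})

test_that("filter_dark_sky drops dark patches and keeps threshold cases", {
  black <- array(0, c(8, 8, 3))
  white <- array(255, c(8, 8, 3))
  at_threshold <- array(102, c(8, 8, 3))   # V = 102/255 = 0.4 exactly
  kept <- filter_dark_sky(list(black, white, at_threshold), threshold = 0.4)
  expect_identical(attr(kept, "kept"), c(FALSE, TRUE, TRUE))
  expect_error(filter_dark_sky(list(black), threshold = 0), "threshold")
})

test_that("preprocess_tassel chains crop, segmentation and resize", {
  p <- tassel_params(resolution = 64)
  scene <- make_lab_scene(p, seed = 4)
  out <- preprocess_tassel(scene, resolution = 32)
  expect_identical(dim(out$image), c(32L, 32L, 3L))
  expect_true(all(out$mask %in% c(0, 1)))
  truth <- make_tassel_mask(p, 4)
  truth32 <- (tasselsynth:::cpp_resize_bicubic(truth, 32, 32) >= 0.5) * 1
  expect_gte(mask_iou(out$mask, truth32), 0.8)
})
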