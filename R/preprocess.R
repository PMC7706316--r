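# Dataset preparation: center crop, YCbCr chroma segmentation, bicubic
# resize, [-1,1] normalization, sky saturation/luminance augmentation and
# dark-sky filtering.

#' Otsu threshold of an 8-bit single-channel image
#'
#' Maximizes between-class variance over the 256-bin histogram. Pixels
#' `<= t` fall in class 0. Ties are broken toward the smallest threshold.
#'
#' @param channel Numeric matrix (or vector) with values in 0..255.
#' @return Integer threshold `t` in 0..255.
#' @export
otsu_threshold <- function(channel) {
  v <- round(as.numeric(channel))
  if (length(v) == 0) stop("channel is empty", call. = FALSE)
  if (any(v < 0 | v > 255)) stop("channel values must be in [0, 255]", call. = FALSE)
  h <- tabulate(v + 1L, nbins = 256L)
  if (sum(h > 0) < 2)
    stop("degenerate input: channel has a single gray level", call. = FALSE)
  n <- sum(h)
  levels <- 0:255
  w0 <- cumsum(h)                 # pixels <= t, for t = 0..255
  s0 <- cumsum(h * levels)
  total <- s0[256]
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (total - s0) / w1, 0)
  sigma_b <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  sigma_b[w0 == 0 | w1 == 0] <- 0
  which.max(sigma_b) - 1L         # which.max returns the first (smallest) tie
}

#' Segment a tassel from a lab-scene image via Cb-channel Otsu thresholding
#'
#' The image is converted to YCbCr and the Cb (blue-difference chroma)
#' channel is Otsu-thresholded. The tassel-side class is the class whose
#' mean Cb lies farther from the backdrop mode (the most frequent Cb value);
#' when the distances tie, the smaller class is taken as foreground, since
#' the tassel occupies a minority of the frame. Background pixels of the
#' segmented image are forced to exact black.
#'
#' @param img `ImageRGB` array.
#' @return List with `segmented` (`ImageRGB`, black background) and `mask`
#'   (binary matrix, 1 = tassel).
#' @export
segment_tassel <- function(img) {
  assert_image_rgb(img)
  cb <- quantize8(rgb_to_ycbcr(img)[, , 2])
  t <- otsu_threshold(cb)
  lower <- cb <= t
  counts <- tabulate(cb + 1L, nbins = 256L)
  backdrop_mode <- which.max(counts) - 1L
  mu_lower <- mean(cb[lower]); mu_upper <- mean(cb[!lower])
  d_lower <- abs(mu_lower - backdrop_mode)
  d_upper <- abs(mu_upper - backdrop_mode)
  fg <- if (d_lower > d_upper) lower
        else if (d_upper > d_lower) !lower
        else if (sum(lower) <= sum(!lower)) lower else !lower
  mask <- fg * 1
  segmented <- img
  for (ch in 1:3) {
    plane <- segmented[, , ch]
    plane[!fg] <- 0
    segmented[, , ch] <- plane
  }
  list(segmented = segmented, mask = mask)
}

#' Center crop
#'
#' Extracts the central `h` x `w` window: rows `floor((H-h)/2) + 1 .. + h`
#' and the analogous columns.
#'
#' @param img `ImageRGB` array.
#' @param h,w Crop height and width in pixels; must not exceed the source.
#' @return Cropped `ImageRGB`.
#' @export
crop_center <- function(img, h, w) {
  assert_image_rgb(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  if (h > H || w > W)
    stop("crop size exceeds image dimensions", call. = FALSE)
  r0 <- floor((H - h) / 2)
  c0 <- floor((W - w) / 2)
  img[r0 + seq_len(h), c0 + seq_len(w), , drop = FALSE]
}

#' Bicubic resize to a square resolution
#'
#' Catmull-Rom bicubic resampling per channel, clipped back to \[0, 255\].
#'
#' @param img `ImageRGB` array or single-channel matrix.
#' @param resolution Output side in pixels (>= 1).
#' @return Resized image of the same kind as the input.
#' @export
resize_image <- function(img, resolution) {
  if (resolution < 1) stop("resolution must be >= 1", call. = FALSE)
  if (is.matrix(img))
    return(quantize8(cpp_resize_bicubic(img, resolution, resolution)))
  assert_image_rgb(img)
  out <- array(0, c(resolution, resolution, 3))
  for (ch in 1:3)
    out[, , ch] <- cpp_resize_bicubic(img[, , ch], resolution, resolution)
  quantize8(out)
}

#' Map an 8-bit image to the \[-1, 1\] range (and back)
#'
#' `normalize_image` applies `x / 127.5 - 1`; `denormalize_image` inverts it
#' and rounds back to 8-bit, so the round trip is exact on all 256 levels.
#'
#' @param img 8-bit array (any shape).
#' @return Array of the same shape in \[-1, 1\].
#' @export
normalize_image <- function(img) img / 127.5 - 1

#' @rdname normalize_image
#' @param x Array in \[-1, 1\].
#' @export
denormalize_image <- function(x) quantize8((x + 1) * 127.5)

#' Saturation/luminance augmentation for sky patches
#'
#' Converts to HSV, scales saturation by `sat_scale` and, when given,
#' value by `lum_scale` (both clipped to \[0, 1\]); hue is unchanged.
#'
#' @param img `ImageRGB` array.
#' @param sat_scale Positive saturation multiplier (0.6 in the training
#'   recipe).
#' @param lum_scale Optional positive luminance multiplier (1.3 in the
#'   training recipe); `NULL` leaves luminance untouched.
#' @return Augmented `ImageRGB`.
#' @export
augment_sky <- function(img, sat_scale = 0.6, lum_scale = NULL) {
  assert_image_rgb(img)
  if (sat_scale <= 0) stop("sat_scale must be > 0", call. = FALSE)
  hsv <- rgb_to_hsv_img(img)
  hsv[, , 2] <- clamp(hsv[, , 2] * sat_scale, 0, 1)
  if (!is.null(lum_scale)) {
    if (lum_scale <= 0) stop("lum_scale must be > 0", call. = FALSE)
    hsv[, , 3] <- clamp(hsv[, , 3] * lum_scale, 0, 1)
  }
  hsv_to_rgb_img(hsv)
}

#' Drop dark sky patches from a training set
#'
#' Keeps an image iff its mean HSV value (brightness) relative to the
#' maximum is at least `threshold`. The darkness criterion is a documented
#' heuristic; images exactly at the threshold are kept.
#'
#' @param images List of `ImageRGB` arrays.
#' @param threshold Fraction of maximum luminance in (0, 1); default 0.35.
#' @return The kept sublist, with attribute `"kept"` holding the logical
#'   keep vector.
#' @export
filter_dark_sky <- function(images, threshold = 0.35) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  keep <- vapply(images, function(img) {
    v <- rgb_to_hsv_img(img)[, , 3]
    mean(v) >= threshold
  }, logical(1))
  structure(images[keep], kept = keep)
}

#' Full tassel patch preparation chain
#'
#' Center crop (optional), chroma segmentation, and bicubic resize — the
#' steps that turn a raw lab capture into a training patch.
#'
#' @param img Raw `ImageRGB`.
#' @param crop Optional `c(h, w)` center-crop size.
#' @param resolution Output resolution (default 128).
#' @return List with `image` (segmented, resized patch) and `mask` (resized,
#'   re-binarized ground mask).
#' @export
preprocess_tassel <- function(img, crop = NULL, resolution = 128) {
  if (!is.null(crop)) img <- crop_center(img, crop[1], crop[2])
  seg <- segment_tassel(img)
  out <- resize_image(seg$segmented, resolution)
  m <- cpp_resize_bicubic(seg$mask, resolution, resolution)
  list(image = out, mask = (m >= 0.5) * 1)
}
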