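# Color-space conversions on H x W x 3 arrays.
#
# YCbCr uses the ITU-R BT.601 full-range (JPEG) matrix, the common
# still-image convention; Y, Cb, Cr all span [0, 255] with chroma
# centered at 128.

#' Convert an RGB image to YCbCr (BT.601 full range)
#'
#' @param img H x W x 3 RGB array, values 0..255.
#' @return H x W x 3 array with channels Y, Cb, Cr (unquantized doubles).
#' @export
rgb_to_ycbcr <- function(img) {
  assert_image_rgb(img)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  out <- array(0, dim(img))
  out[, , 1] <- 0.299 * r + 0.587 * g + 0.114 * b
  out[, , 2] <- 128 - 0.168736 * r - 0.331264 * g + 0.5 * b
  out[, , 3] <- 128 + 0.5 * r - 0.418688 * g - 0.081312 * b
  out
}

#' Convert a YCbCr image back to 8-bit RGB
#'
#' @param ycc H x W x 3 array with channels Y, Cb, Cr.
#' @return H x W x 3 RGB array, quantized to 0..255.
#' @export
ycbcr_to_rgb <- function(ycc) {
  y <- ycc[, , 1]; cb <- ycc[, , 2] - 128; cr <- ycc[, , 3] - 128
  out <- array(0, dim(ycc))
  out[, , 1] <- y + 1.402 * cr
  out[, , 2] <- y - 0.344136 * cb - 0.714136 * cr
  out[, , 3] <- y + 1.772 * cb
  quantize8(out)
}

# 8-bit luma channel (rounded Y), used by SSIM and Y-channel thresholding.
luma8 <- function(img) {
  if (is.matrix(img)) return(quantize8(img))
  quantize8(rgb_to_ycbcr(img)[, , 1])
}

# HSV conversion via grDevices::rgb2hsv; returns H x W x 3 with H in [0,1].
rgb_to_hsv_img <- function(img) {
  assert_image_rgb(img)
  m <- rgb2hsv(matrix(aperm(img, c(3, 1, 2)), nrow = 3), maxColorValue = 255)
  aperm(array(m, c(3, dim(img)[1], dim(img)[2])), c(2, 3, 1))
}

hsv_to_rgb_img <- function(hsv) {
  h <- hsv[, , 1] * 6; s <- hsv[, , 2]; v <- hsv[, , 3]
  i <- floor(h) %% 6; f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  # assemble explicitly per sextant
  rr <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
        ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  gg <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
        ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  bb <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
        ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  out <- array(0, dim(hsv))
  out[, , 1] <- rr; out[, , 2] <- gg; out[, , 3] <- bb
  quantize8(out * 255)
}
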