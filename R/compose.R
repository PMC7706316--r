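# Compositing: turn a generated tassel patch and sky patch into a
# field-style image with its segmentation mask. Pipeline: luminance
# correction -> Y-channel Otsu mask -> x2 bicubic upscale -> seeded shift ->
# mask merge -> horizontal edge blending -> x2 downscale.

#' Compositing configuration
#'
#' @param luminance_factor Y-channel multiplier in (0, 1\] applied to the
#'   tassel before masking; generated tassels come out brighter than real
#'   ones, so the default darkens them to 0.85.
#' @param shift_range Maximum absolute shift (pixels, per axis, at the
#'   upscaled resolution) applied to the tassel before merging.
#' @param blend_enabled Apply weighted edge blending after the merge?
#' @param seed Integer seed for the shift draw.
#' @return A `compose_config` list.
#' @export
compose_config <- function(luminance_factor = 0.85, shift_range = 8,
                           blend_enabled = TRUE, seed = 1) {
  if (luminance_factor <= 0 || luminance_factor > 1)
    stop("luminance_factor must be in (0, 1]", call. = FALSE)
  if (shift_range < 0) stop("shift_range must be >= 0", call. = FALSE)
  structure(list(luminance_factor = luminance_factor,
                 shift_range = as.integer(shift_range),
                 blend_enabled = isTRUE(blend_enabled),
                 seed = as.integer(seed)),
            class = "compose_config")
}

#' Reduce image luminance in YCbCr space
#'
#' Scales the Y channel by `factor`, leaving Cb and Cr untouched.
#'
#' @param img `ImageRGB` array.
#' @param factor Multiplier in (0, 1].
#' @return Darkened `ImageRGB`.
#' @export
reduce_luminance <- function(img, factor = 0.85) {
  assert_image_rgb(img)
  if (factor <= 0 || factor > 1)
    stop("factor must be in (0, 1]", call. = FALSE)
  ycc <- rgb_to_ycbcr(img)
  ycc[, , 1] <- ycc[, , 1] * factor
  ycbcr_to_rgb(ycc)
}

#' Extract a tassel mask from a generated patch via Y-channel thresholding
#'
#' The Y (luma) channel gives the maximum separation between the bright
#' tassel and the dark background; Otsu's threshold is applied and the
#' brighter class is taken as foreground.
#'
#' @param img `ImageRGB` array with a bright object on a dark background.
#' @return Binary matrix, 1 = tassel.
#' @export
extract_tassel_mask <- function(img) {
  assert_image_rgb(img)
  y <- luma8(img)
  t <- otsu_threshold(y)
  (y > t) * 1
}

#' Merge a foreground and a background through a binary mask
#'
#' Per pixel: `mask * fg + (1 - mask) * bg`. No new colors are introduced.
#'
#' @param fg,bg `ImageRGB` arrays of identical size.
#' @param mask Binary matrix of the same height/width.
#' @return Merged `ImageRGB`.
#' @export
merge_images <- function(fg, bg, mask) {
  assert_image_rgb(fg, "fg"); assert_image_rgb(bg, "bg"); assert_mask(mask)
  if (!all(dim(fg) == dim(bg)) || !all(dim(mask) == dim(fg)[1:2]))
    stop("fg, bg and mask dimensions must agree", call. = FALSE)
  out <- bg
  for (ch in 1:3) {
    f <- fg[, , ch]; b <- bg[, , ch]
    out[, , ch] <- mask * f + (1 - mask) * b
  }
  out
}

#' Blend mask edges with weighted row-neighbor averages
#'
#' For each row, the first and last foreground pixel of every maximal
#' mask run is an edge pixel. With `L` and `R` the pre-blend values of its
#' left and right row neighbors, the three pixels are reassigned
#' simultaneously per channel: edge to `0.5 L + 0.5 R`, the left neighbor
#' to `0.75 L + 0.25 R` and the right neighbor to `0.25 L + 0.75 R`.
#' Edges whose neighbor falls outside the image are skipped. A mask with no
#' transitions leaves the image unchanged.
#'
#' @param img `ImageRGB` array (the merged image).
#' @param mask Binary matrix marking the foreground.
#' @return Blended `ImageRGB`.
#' @export
blend_edges <- function(img, mask) {
  assert_image_rgb(img); assert_mask(mask)
  if (!all(dim(mask) == dim(img)[1:2]))
    stop("img and mask dimensions must agree", call. = FALSE)
  W <- ncol(mask)
  pre <- img
  for (row in seq_len(nrow(mask))) {
    m <- mask[row, ]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    fg_runs <- which(r$values == 1)
    edges <- unique(as.integer(c(starts[fg_runs], ends[fg_runs])))
    for (e in edges) {
      if (e <= 1L || e >= W) next           # missing a neighbor: skip
      L <- pre[row, e - 1L, ]
      R <- pre[row, e + 1L, ]
      img[row, e, ]      <- 0.5  * L + 0.5  * R
      img[row, e - 1L, ] <- 0.75 * L + 0.25 * R
      img[row, e + 1L, ] <- 0.25 * L + 0.75 * R
    }
  }
  quantize8(img)
}

# Integer translate; exposed background filled with `fill`.
shift_plane <- function(m, dy, dx, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  H <- nrow(m); W <- ncol(m)
  src_r <- seq_len(H) - dy; src_c <- seq_len(W) - dx
  ok_r <- src_r >= 1 & src_r <= H; ok_c <- src_c >= 1 & src_c <= W
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Compose a field-style image from a tassel patch and a sky patch
#'
#' Applies luminance correction, extracts the Y-channel Otsu mask, upscales
#' tassel, sky and mask by 2 (bicubic; the mask is re-binarized at 0.5),
#' shifts the tassel and mask by a seeded integer offset (clipped so the
#' tassel bounding box stays inside the frame, with a warning), merges
#' through the mask, optionally blends edges, and scales back down by 2.
#'
#' @param tassel,sky `ImageRGB` arrays of the same square resolution.
#' @param config A [compose_config()].
#' @return List with `merged` (`ImageRGB` at the input resolution) and
#'   `mask` (binary matrix, the label paired with the image).
#' @export
compose_field_image <- function(tassel, sky, config = compose_config()) {
  assert_image_rgb(tassel, "tassel"); assert_image_rgb(sky, "sky")
  if (!all(dim(tassel) == dim(sky)))
    stop("tassel and sky must have the same dimensions", call. = FALSE)
  res <- dim(tassel)[1]
  fg <- reduce_luminance(tassel, config$luminance_factor)
  mask <- extract_tassel_mask(fg)
  if (sum(mask) == 0) stop("degenerate mask: no foreground", call. = FALSE)
  up <- 2L * res
  fg2 <- resize_image(fg, up)
  bg2 <- resize_image(sky, up)
  mask2 <- (cpp_resize_bicubic(mask, up, up) >= 0.5) * 1
  ## seeded shift, clipped so the tassel bbox stays inside the frame
  sh <- with_seed(config$seed,
                  sample(-config$shift_range:config$shift_range, 2, replace = TRUE))
  rows <- range(which(rowSums(mask2) > 0))
  cols <- range(which(colSums(mask2) > 0))
  dy <- clamp(sh[1], 1 - rows[1], up - rows[2])
  dx <- clamp(sh[2], 1 - cols[1], up - cols[2])
  if (dy != sh[1] || dx != sh[2])
    warning("shift clipped to keep the tassel inside the frame")
  fg2s <- fg2
  for (ch in 1:3) fg2s[, , ch] <- shift_plane(fg2[, , ch], dy, dx)
  mask2s <- shift_plane(mask2, dy, dx)
  merged <- merge_images(fg2s, bg2, mask2s)
  if (config$blend_enabled) merged <- blend_edges(merged, mask2s)
  out <- resize_image(merged, res)
  mask_out <- (cpp_resize_bicubic(mask2s, res, res) >= 0.5) * 1
  list(merged = out, mask = mask_out)
}
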