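# Shared helpers: seeded evaluation, 8-bit image validation, mask utilities.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Round to 8-bit integer range.
quantize8 <- function(x) clamp(round(x), 0, 255)

assert_image_rgb <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  if (any(!is.finite(img)) || any(img < 0) || any(img > 255))
    stop(sprintf("`%s` must hold 8-bit values in [0, 255]", arg), call. = FALSE)
  invisible(img)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1)))
    stop(sprintf("`%s` must be a binary H x W matrix", arg), call. = FALSE)
  invisible(mask)
}

#' Intersection over union of two binary masks
#'
#' @param a,b Binary matrices of identical dimensions.
#' @return IoU in \[0, 1\]; defined as 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  assert_mask(a, "a"); assert_mask(b, "b")
  stopifnot(all(dim(a) == dim(b)))
  un <- sum(a | b)
  if (un == 0) return(1)
  sum(a & b) / un
}

# Polynomial rolling hash over the serialized object (mod 2^31 - 1);
# used to bind checkpoints to their architecture spec.
object_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

#' Read an RGB image from a PNG or JPEG file
#'
#' Returns an 8-bit H x W x 3 array; grayscale files are replicated across
#' channels and alpha channels are dropped.
#'
#' @param path File path.
#' @return `ImageRGB` array with values in 0..255.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3] == 1L) img <- img[, , c(1, 1, 1), drop = FALSE]
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  quantize8(img * 255)
}

#' Write an RGB image (or binary mask) to a PNG file
#'
#' @param img H x W x 3 array in 0..255, or a binary matrix.
#' @param path Output file path.
#' @export
write_image <- function(img, path) {
  if (is.matrix(img)) {
    png::writePNG(img, path)
  } else {
    assert_image_rgb(img)
    png::writePNG(img / 255, path)
  }
  invisible(path)
}
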