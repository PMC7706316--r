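# Procedural fixtures: tassel-like silhouettes, sky-like patches, lab-scene
# images and annotation matrices. These emulate the statistical structure the
# pipeline assumes (bright plant object on an exact-black background, bimodal
# chroma in lab scenes, blue-dominant sky) so every downstream stage can be
# exercised without any external dataset.

#' Parameters for the procedural tassel renderer
#'
#' A tassel is drawn as a central vertical spike plus `n_branches` angled
#' strokes, in brownish tones on an exact-black background. The background
#' is exactly (0,0,0) and strokes are painted without anti-aliasing, so the
#' ground-truth mask is exactly the set of non-black pixels.
#'
#' @param resolution Image side in pixels (>= 16).
#' @param n_branches Number of lateral branches (>= 0).
#' @param spike_height_frac Spike height as a fraction of image height, in
#'   (0, 1].
#' @param branch_angle_range Maximum deviation of a branch from vertical, in
#'   degrees.
#' @param color_base RGB triple (0..255) of the base brownish tassel color.
#' @param jitter Per-pixel brightness jitter amplitude, a fraction in \[0, 1).
#' @return A `tassel_params` list, validated.
#' @export
tassel_params <- function(resolution = 128, n_branches = 8,
                          spike_height_frac = 0.7, branch_angle_range = 60,
                          color_base = c(150, 100, 50), jitter = 0.25) {
  if (resolution < 16) stop("resolution must be >= 16", call. = FALSE)
  if (n_branches < 0) stop("n_branches must be >= 0", call. = FALSE)
  if (spike_height_frac <= 0 || spike_height_frac > 1)
    stop("spike_height_frac must be in (0, 1]", call. = FALSE)
  if (length(color_base) != 3 || any(color_base < 0) || any(color_base > 255))
    stop("color_base must be an RGB triple in [0, 255]", call. = FALSE)
  if (jitter < 0 || jitter >= 1) stop("jitter must be in [0, 1)", call. = FALSE)
  structure(list(resolution = as.integer(resolution),
                 n_branches = as.integer(n_branches),
                 spike_height_frac = spike_height_frac,
                 branch_angle_range = branch_angle_range,
                 color_base = color_base, jitter = jitter),
            class = "tassel_params")
}

#' Parameters for the procedural sky renderer
#'
#' A sky patch is a vertical gradient between two blue-dominant colors with
#' additive multi-octave cloud texture pulling pixels toward white.
#'
#' @param resolution Image side in pixels (>= 16).
#' @param gradient_top,gradient_bottom RGB triples; the blue channel must
#'   not fall below the red channel (blue-dominant sky).
#' @param cloud_density Cloud coverage fraction in \[0, 1\].
#' @param cloud_scale Characteristic cloud blob size in pixels.
#' @return A `sky_params` list, validated.
#' @export
sky_params <- function(resolution = 128, gradient_top = c(60, 120, 210),
                       gradient_bottom = c(140, 185, 235),
                       cloud_density = 0.4, cloud_scale = 32) {
  if (resolution < 16) stop("resolution must be >= 16", call. = FALSE)
  for (gcol in list(gradient_top, gradient_bottom)) {
    if (length(gcol) != 3 || any(gcol < 0) || any(gcol > 255))
      stop("gradient colors must be RGB triples in [0, 255]", call. = FALSE)
    if (gcol[3] < gcol[1])
      stop("gradient colors must have blue >= red", call. = FALSE)
  }
  if (cloud_density < 0 || cloud_density > 1)
    stop("cloud_density must be in [0, 1]", call. = FALSE)
  structure(list(resolution = as.integer(resolution),
                 gradient_top = gradient_top,
                 gradient_bottom = gradient_bottom,
                 cloud_density = cloud_density,
                 cloud_scale = cloud_scale),
            class = "sky_params")
}

# Paint a thick line segment into a logical mask, hard pixels (no AA).
paint_segment <- function(mask, r0, c0, r1, c1, thickness) {
  n <- max(2L, ceiling(2 * max(abs(r1 - r0), abs(c1 - c0))) + 1L)
  rs <- round(seq(r0, r1, length.out = n))
  cs <- round(seq(c0, c1, length.out = n))
  half <- floor((thickness - 1) / 2)
  H <- nrow(mask); W <- ncol(mask)
  for (d in -half:(thickness - 1 - half)) {
    rr <- clamp(rs, 1, H)
    cc <- clamp(cs + d, 1, W)
    mask[cbind(rr, cc)] <- TRUE
  }
  mask
}

# Shared geometry + shading for tassel image/mask pairs: everything random
# is drawn under the caller's seed so image and mask calls agree exactly.
render_tassel <- function(params, seed) {
  stopifnot(inherits(params, "tassel_params"))
  with_seed(seed, {
    res <- params$resolution
    mask <- matrix(FALSE, res, res)
    cx <- round(res / 2 + runif(1, -1, 1) * params$jitter * res * 0.1)
    spike_h <- max(2L, round(params$spike_height_frac * res))
    top <- max(1L, round((res - spike_h) / 2))
    bottom <- min(res, top + spike_h - 1L)
    thick <- max(1L, round(res * 0.03))
    mask <- paint_segment(mask, bottom, cx, top, cx, thick)
    if (params$n_branches > 0) {
      for (i in seq_len(params$n_branches)) {
        r_start <- round(runif(1, top, top + 0.7 * spike_h))
        ang <- runif(1, 0, params$branch_angle_range) * pi / 180  # from vertical
        side <- if (i %% 2 == 0) -1 else 1
        len <- runif(1, 0.12, 0.3) * res
        r_end <- r_start - len * cos(ang)
        c_end <- cx + side * len * sin(ang)
        mask <- paint_segment(mask, r_start, cx, clamp(r_end, 1, res),
                              clamp(c_end, 1, res),
                              max(1L, round(thick / 2)))
      }
    }
    img <- array(0, c(res, res, 3))
    n_fg <- sum(mask)
    # per-pixel brightness jitter; painted pixels are kept strictly non-black
    shade <- 1 + runif(n_fg, -1, 1) * params$jitter
    for (ch in 1:3) {
      plane <- matrix(0, res, res)
      plane[mask] <- clamp(round(params$color_base[ch] * shade), 1, 255)
      img[, , ch] <- plane
    }
    list(img = img, mask = mask * 1)
  })
}

#' Render a tassel-like training patch
#'
#' Deterministic for a fixed seed; the exact ground-truth mask of the same
#' render is available from [make_tassel_mask()] with identical arguments.
#'
#' @param params A [tassel_params()] object.
#' @param seed Integer seed.
#' @return `ImageRGB` array (resolution x resolution x 3, 0..255).
#' @export
make_tassel_image <- function(params = tassel_params(), seed = 1) {
  render_tassel(params, seed)$img
}

#' Ground-truth mask of a rendered tassel
#'
#' @inheritParams make_tassel_image
#' @return Binary matrix; 1 marks painted (foreground) pixels.
#' @export
make_tassel_mask <- function(params = tassel_params(), seed = 1) {
  render_tassel(params, seed)$mask
}

# Multi-octave smoothed random field in [0,1], upsampled bicubically.
cloud_field <- function(res, scale) {
  field <- matrix(0, res, res)
  amp <- 1; total <- 0
  for (octave in 0:2) {
    n <- max(2L, round(res / max(2, scale / 2^octave)) + 1L)
    coarse <- matrix(runif(n * n), n, n)
    field <- field + amp * cpp_resize_bicubic(coarse, res, res)
    total <- total + amp
    amp <- amp / 2
  }
  clamp(field / total, 0, 1)
}

#' Render a sky-like background patch
#'
#' A vertical blue gradient plus seeded smooth cloud texture that pulls
#' pixels toward white. With defaults, no pixel has red exceeding blue.
#'
#' @param params A [sky_params()] object.
#' @param seed Integer seed.
#' @return `ImageRGB` array.
#' @export
make_sky_image <- function(params = sky_params(), seed = 1) {
  stopifnot(inherits(params, "sky_params"))
  with_seed(seed, {
    res <- params$resolution
    frac <- (seq_len(res) - 1) / (res - 1)
    img <- array(0, c(res, res, 3))
    for (ch in 1:3) {
      col_line <- params$gradient_top[ch] +
        frac * (params$gradient_bottom[ch] - params$gradient_top[ch])
      img[, , ch] <- matrix(col_line, res, res)
    }
    if (params$cloud_density > 0) {
      f <- cloud_field(res, params$cloud_scale)
      # soft threshold so that `cloud_density` controls coverage
      alpha <- clamp((f - (1 - params$cloud_density)) / 0.35, 0, 1)
      for (ch in 1:3) img[, , ch] <- img[, , ch] + alpha * (255 - img[, , ch])
    }
    quantize8(img)
  })
}

#' Render a lab-scene image: a tassel over a uniform bluish backdrop
#'
#' Emulates indoor captures with a high-Cb backdrop, the input the chroma
#' segmentation stage assumes. The ground-truth mask is
#' [make_tassel_mask()] with the same `params` and `seed`.
#'
#' @inheritParams make_tassel_image
#' @param backdrop RGB triple of the uniform backdrop. Segmentation assumes
#'   a bluish (high-Cb) backdrop; a backdrop matching the tassel color
#'   produces a chroma-degenerate scene that [segment_tassel()] rejects.
#' @return `ImageRGB` array.
#' @export
make_lab_scene <- function(params = tassel_params(), backdrop = c(150, 180, 230),
                           seed = 1) {
  if (length(backdrop) != 3 || any(backdrop < 0) || any(backdrop > 255))
    stop("backdrop must be an RGB triple in [0, 255]", call. = FALSE)
  r <- render_tassel(params, seed)
  img <- r$img
  fg <- r$mask == 1
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[!fg] <- backdrop[ch]
    img[, , ch] <- plane
  }
  img
}

#' Simulate a categorical annotation matrix
#'
#' Each item gets a majority (true) label; every annotator independently
#' reports a different label with probability `disagreement_rate`.
#'
#' @param n_items Number of annotated items (>= 1).
#' @param k_annotators Number of annotators (>= 2).
#' @param disagreement_rate Per-annotator flip probability in \[0, 1\].
#' @param n_classes Number of label classes (default 2).
#' @param seed Integer seed.
#' @return Integer matrix `n_items` x `k_annotators` of labels in
#'   `1..n_classes`.
#' @export
make_annotation_matrix <- function(n_items, k_annotators, disagreement_rate,
                                   n_classes = 2, seed = 1) {
  if (n_items < 1) stop("n_items must be >= 1", call. = FALSE)
  if (k_annotators < 2) stop("k_annotators must be >= 2", call. = FALSE)
  if (disagreement_rate < 0 || disagreement_rate > 1)
    stop("disagreement_rate must be in [0, 1]", call. = FALSE)
  with_seed(seed, {
    truth <- sample.int(n_classes, n_items, replace = TRUE)
    m <- matrix(truth, n_items, k_annotators)
    flip <- matrix(runif(n_items * k_annotators) < disagreement_rate,
                   n_items, k_annotators)
    if (any(flip)) {
      shift <- sample.int(n_classes - 1, sum(flip), replace = TRUE)
      m[flip] <- (m[flip] - 1 + shift) %% n_classes + 1
    }
    m
  })
}

#' Write a set of fixtures to disk with masks and a manifest
#'
#' @param type One of `"tassels"`, `"skies"`, `"labscenes"`.
#' @param n Number of images.
#' @param out_dir Output directory (created if missing); images as PNG, tassel
#'   and lab-scene sets also get a `masks/` subdirectory, plus
#'   `manifest.json` recording filenames, seeds and parameters.
#' @param resolution Image side in pixels.
#' @param seed Base seed; image i uses `seed + i - 1`.
#' @return Invisibly, the manifest as a list.
#' @export
write_fixture_set <- function(type = c("tassels", "skies", "labscenes"),
                              n, out_dir, resolution = 128, seed = 1) {
  type <- match.arg(type)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  has_mask <- type != "skies"
  if (has_mask)
    dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  params <- if (type == "skies") sky_params(resolution = resolution)
            else tassel_params(resolution = resolution)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    si <- seed + i - 1
    img <- switch(type,
                  tassels   = make_tassel_image(params, si),
                  skies     = make_sky_image(params, si),
                  labscenes = make_lab_scene(params, seed = si))
    prefix <- c(tassels = "tassel", skies = "sky", labscenes = "labscene")[[type]]
    fn <- sprintf("%s_%04d.png", prefix, i)
    write_image(img, file.path(out_dir, fn))
    if (has_mask)
      write_image(make_tassel_mask(params, si), file.path(out_dir, "masks", fn))
    entries[[i]] <- list(file = fn, seed = si)
  }
  manifest <- list(type = type, resolution = resolution,
                   params = unclass(params), images = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
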