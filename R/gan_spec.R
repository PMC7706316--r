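# Architecture descriptions for the DC-GAN variant: stage tables,
# batch-norm flags and residual attachment sets, plus YAML round-tripping
# and spec-bound checkpoints.
#
# Stage conventions (all learned kernels 4x4):
#   generator:      stage 1 projects the latent to 4x4 (transposed conv,
#                   stride 1, no padding); stages 2..n are transposed convs
#                   (stride 2, padding 1) that double the resolution; ReLU
#                   after every stage except the last, which uses tanh.
#   discriminator:  stages 1..n-1 are strided convs (stride 2, padding 1)
#                   halving the resolution down to 4x4; stage n maps 4x4 to
#                   a single sigmoid logit.
# Channel widths follow the DC-GAN doubling scheme: the penultimate
# generator stage has `base_channels` and widths double toward 4x4.

stage_resolutions <- function(resolution) {
  if (resolution < 8 || bitwAnd(resolution, resolution - 1L) != 0)
    stop("resolution must be a power of two >= 8", call. = FALSE)
  2^(2:log2(resolution))
}

#' Build a generator architecture description
#'
#' The generator upsamples a latent vector through `log2(resolution/4) + 1`
#' transposed-convolution stages. Residual paths (upscale-by-2 plus a
#' learned 1x1 channel projection) attach to the stages whose output
#' resolutions are listed in `residual_stages`; the default set covers the
#' 16, 32, 64 and 128 stages, where the deeper tassel network needs them to
#' avoid the degradation problem. Batch-norm layers, when enabled, follow
#' every stage except the last (the standard DC-GAN exception).
#'
#' @param resolution Output image side; a power of two >= 8.
#' @param use_batchnorm Include batch-normalization layers? The tassel and
#'   sky recipes both run without them, which delays discriminator
#'   convergence; `TRUE` exists for ablation experiments.
#' @param residual_stages Integer vector of stage output resolutions that
#'   receive a residual addition; must be a subset of the stage resolutions
#'   (the 4x4 stage cannot, having no predecessor). `NULL` disables
#'   residuals (the sky model).
#' @param base_channels Channel width of the penultimate stage (DC-GAN's
#'   `ngf`); widths double toward the 4x4 stage. Default 64 as in DC-GAN.
#' @param latent_dim Latent vector length (default 100).
#' @param residual_interp Interpolation used by the residual upscale,
#'   `"nearest"` (default) or `"bilinear"`.
#' @return A `gan_spec` object.
#' @export
build_generator_spec <- function(resolution, use_batchnorm = FALSE,
                                 residual_stages = c(16, 32, 64, 128),
                                 base_channels = 64, latent_dim = 100,
                                 residual_interp = c("nearest", "bilinear")) {
  res <- stage_resolutions(resolution)
  n <- length(res)
  channels <- c(base_channels * 2^((n - 2):1), base_channels, 3)[seq_len(n)]
  channels[n] <- 3
  residual_stages <- as.integer(intersect(residual_stages, res[-1]))
  if (length(setdiff(residual_stages, res)))
    stop("residual_stages must be a subset of stage resolutions", call. = FALSE)
  stages <- data.frame(
    resolution = res,
    out_channels = channels,
    batchnorm = use_batchnorm & seq_len(n) < n,
    activation = c(rep("relu", n - 1), "tanh"),
    stringsAsFactors = FALSE
  )
  structure(list(role = "generator", resolution = as.integer(resolution),
                 latent_dim = as.integer(latent_dim), stages = stages,
                 use_batchnorm = use_batchnorm,
                 residual_stages = sort(residual_stages),
                 residual_interp = match.arg(residual_interp),
                 final_activation = "tanh"),
            class = "gan_spec")
}

#' Build a discriminator architecture description
#'
#' Mirrors the generator: strided 4x4 convolutions with leaky-ReLU (slope
#' 0.2) halve the resolution down to 4x4, then a final convolution produces
#' one sigmoid probability. Batch norm, when enabled, skips the first and
#' last stages (DC-GAN convention).
#'
#' @inheritParams build_generator_spec
#' @param base_channels Channel width after the first convolution (`ndf`).
#' @return A `gan_spec` object.
#' @export
build_discriminator_spec <- function(resolution, use_batchnorm = FALSE,
                                     base_channels = 64) {
  res <- stage_resolutions(resolution)
  n <- length(res)
  out_res <- c(rev(res)[-1], 1L)
  channels <- c(base_channels * 2^(0:(n - 2)), 1)
  stages <- data.frame(
    resolution = out_res,
    out_channels = channels,
    batchnorm = use_batchnorm & seq_len(n) > 1 & seq_len(n) < n,
    activation = c(rep("lrelu", n - 1), "sigmoid"),
    stringsAsFactors = FALSE
  )
  structure(list(role = "discriminator", resolution = as.integer(resolution),
                 latent_dim = NA_integer_, stages = stages,
                 use_batchnorm = use_batchnorm,
                 residual_stages = integer(0),
                 residual_interp = "nearest",
                 final_activation = "sigmoid"),
            class = "gan_spec")
}

#' @export
print.gan_spec <- function(x, ...) {
  cat(sprintf("<gan_spec: %s, %dx%d, %d stages%s%s>\n", x$role,
              x$resolution, x$resolution, nrow(x$stages),
              if (x$use_batchnorm) ", batchnorm" else "",
              if (length(x$residual_stages))
                paste0(", residual@{", paste(x$residual_stages, collapse = ","), "}")
              else ""))
  print(x$stages)
  invisible(x)
}

#' Serialize a GAN spec to YAML (and back)
#'
#' @param spec A `gan_spec`.
#' @param path Output (input) file path.
#' @return `read_gan_spec` returns the reconstructed `gan_spec`.
#' @export
write_gan_spec <- function(spec, path) {
  stopifnot(inherits(spec, "gan_spec"))
  obj <- unclass(spec)
  obj$stages <- as.list(spec$stages)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_gan_spec
#' @export
read_gan_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$stages <- data.frame(obj$stages, stringsAsFactors = FALSE)
  obj$resolution <- as.integer(obj$resolution)
  obj$latent_dim <- as.integer(obj$latent_dim)
  obj$residual_stages <- as.integer(unlist(obj$residual_stages))
  structure(obj, class = "gan_spec")
}

#' Save or load a network checkpoint bound to its architecture spec
#'
#' A checkpoint is a single file holding the parameters, the spec, and a
#' hash of the spec; loading verifies the hash and (optionally) that the
#' checkpoint matches an expected spec.
#'
#' @param params A `net_params` object from [init_net_params()] or training.
#' @param spec The matching `gan_spec`.
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(params, spec, path) {
  stopifnot(inherits(spec, "gan_spec"))
  saveRDS(list(params = params, spec = spec, spec_hash = object_hash(spec)),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expected_spec Optional `gan_spec` the checkpoint must match.
#' @return `load_checkpoint` returns a list with `params` and `spec`.
#' @export
load_checkpoint <- function(path, expected_spec = NULL) {
  ck <- readRDS(path)
  if (!identical(object_hash(ck$spec), ck$spec_hash))
    stop("checkpoint spec hash mismatch", call. = FALSE)
  if (!is.null(expected_spec) &&
      !identical(object_hash(expected_spec), ck$spec_hash))
    stop("checkpoint does not match the expected spec", call. = FALSE)
  ck[c("params", "spec")]
}
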