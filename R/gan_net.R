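# Network parameters, forward passes and backpropagation for the DC-GAN
# variant. Feature maps travel as (C, H, W, B) arrays so each convolution
# is a single BLAS matrix product in the compiled kernels.
#
# Weight storage:
#   generator stage i:      Wt (Cin x Cout*16), bias (Cout)   [transposed conv]
#   discriminator stage i:  W  (Cout x Cin*16), bias (Cout)   [strided conv]
#   residual projection:    P  (Ct x Cs), a learned 1x1 convolution, no bias
#   batch norm:             gamma, beta per channel

relu_fwd <- function(x) x * (x > 0)
lrelu_fwd <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
lrelu_bwd <- function(g, x, slope = 0.2) g * ifelse(x > 0, 1, slope)

# 2x spatial upscale of a (C,H,W,B) tensor.
upscale2 <- function(x, method = "nearest") {
  d <- dim(x)
  if (method == "nearest") {
    return(x[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2), ,
             drop = FALSE])
  }
  # bilinear with pixel-center alignment, edges clamped
  A <- bilinear2_matrix(d[2])
  Bm <- bilinear2_matrix(d[3])
  apply_sep(x, A, Bm)
}

# adjoint of upscale2 (used by backprop)
downsum2 <- function(g, method = "nearest") {
  d <- dim(g)
  if (method == "nearest") {
    oh <- seq(1, d[2], by = 2); ow <- seq(1, d[3], by = 2)
    return(g[, oh, ow, , drop = FALSE] + g[, oh + 1, ow, , drop = FALSE] +
           g[, oh, ow + 1, , drop = FALSE] + g[, oh + 1, ow + 1, , drop = FALSE])
  }
  A <- t(bilinear2_matrix(d[2] / 2))
  Bm <- t(bilinear2_matrix(d[3] / 2))
  apply_sep(g, A, Bm)
}

# (2n x n) interpolation matrix for factor-2 bilinear upscaling.
bilinear2_matrix <- function(n) {
  A <- matrix(0, 2 * n, n)
  for (i in seq_len(2 * n)) {
    src <- (i - 0.5) / 2 - 0.5        # 0-based source coordinate
    j0 <- clamp(floor(src), 0, n - 1)
    j1 <- clamp(j0 + 1, 0, n - 1)
    w1 <- clamp(src - j0, 0, 1)
    A[i, j0 + 1] <- A[i, j0 + 1] + (1 - w1)
    A[i, j1 + 1] <- A[i, j1 + 1] + w1
  }
  A
}

# y[c,:,:,b] = A %*% x[c,:,:,b] %*% t(B) applied over channels and batch
apply_sep <- function(x, A, Bm) {
  d <- dim(x)
  out <- array(0, c(d[1], nrow(A), nrow(Bm), d[4]))
  for (b in seq_len(d[4]))
    for (c in seq_len(d[1]))
      out[c, , , b] <- A %*% x[c, , , b] %*% t(Bm)
  out
}

stage_geom <- function(spec, i) {
  if (spec$role == "generator") {
    if (i == 1) list(k = 4L, s = 1L, p = 0L) else list(k = 4L, s = 2L, p = 1L)
  } else {
    n <- nrow(spec$stages)
    if (i == n) list(k = 4L, s = 1L, p = 0L) else list(k = 4L, s = 2L, p = 1L)
  }
}

stage_in_channels <- function(spec, i) {
  if (i > 1) return(spec$stages$out_channels[i - 1])
  if (spec$role == "generator") spec$latent_dim else 3L
}

#' Initialize network parameters for an architecture spec
#'
#' Kernels are drawn from a zero-mean Gaussian with standard deviation 0.02
#' (DC-GAN convention); biases start at zero, batch-norm scale/shift at 1/0.
#' Residual 1x1 projections are learned parameters with the same
#' initialization.
#'
#' @param spec A `gan_spec`.
#' @param seed Integer seed for the weight draw.
#' @return A `net_params` object: a named list of parameter tensors plus the
#'   spec hash.
#' @export
init_net_params <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "gan_spec"))
  with_seed(seed, {
    tensors <- list()
    n <- nrow(spec$stages)
    for (i in seq_len(n)) {
      cin <- stage_in_channels(spec, i)
      cout <- spec$stages$out_channels[i]
      if (spec$role == "generator") {
        tensors[[sprintf("s%d.W", i)]] <-
          matrix(rnorm(cin * cout * 16, 0, 0.02), cin, cout * 16)
      } else {
        tensors[[sprintf("s%d.W", i)]] <-
          matrix(rnorm(cout * cin * 16, 0, 0.02), cout, cin * 16)
      }
      tensors[[sprintf("s%d.b", i)]] <- numeric(cout)
      if (spec$stages$batchnorm[i]) {
        tensors[[sprintf("s%d.gamma", i)]] <- rep(1, cout)
        tensors[[sprintf("s%d.beta", i)]] <- numeric(cout)
      }
    }
    for (r in spec$residual_stages) {
      i <- match(r, spec$stages$resolution)
      cs <- stage_in_channels(spec, i)
      ct <- spec$stages$out_channels[i]
      tensors[[sprintf("res%d.P", r)]] <- matrix(rnorm(ct * cs, 0, 0.02), ct, cs)
    }
    structure(list(tensors = tensors, spec_hash = object_hash(spec)),
              class = "net_params")
  })
}

bn_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  m <- matrix(x, d[1])
  mu <- rowMeans(m)
  xc <- m - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  y <- array(gamma * xhat + beta, d)
  list(y = y, xhat = xhat, istd = istd)
}

bn_bwd <- function(g, cache, gamma) {
  d <- dim(g)
  gm <- matrix(g, d[1])
  n <- ncol(gm)
  gxhat <- gm * gamma
  ggamma <- rowSums(gm * cache$xhat)
  gbeta <- rowSums(gm)
  gx <- cache$istd * (gxhat - rowMeans(gxhat) - cache$xhat * rowMeans(gxhat * cache$xhat))
  list(gx = array(gx, d), ggamma = ggamma, gbeta = gbeta)
}

# Generator forward pass over a latent batch z (latent_dim x B).
# Returns the output tensor and, when keep_cache, everything backprop needs.
gen_forward <- function(z, params, spec, residual_enabled = TRUE,
                        keep_cache = FALSE) {
  tn <- params$tensors
  n <- nrow(spec$stages)
  B <- ncol(z)
  a <- array(z, c(nrow(z), 1, 1, B))
  cache <- if (keep_cache) vector("list", n) else NULL
  for (i in seq_len(n)) {
    geom <- stage_geom(spec, i)
    a_prev <- a
    h <- cpp_convt_fwd(a_prev, dim(a_prev), tn[[sprintf("s%d.W", i)]],
                       tn[[sprintf("s%d.b", i)]], geom$k, geom$s, geom$p)
    bn_cache <- NULL
    if (spec$stages$batchnorm[i]) {
      bn <- bn_fwd(h, tn[[sprintf("s%d.gamma", i)]], tn[[sprintf("s%d.beta", i)]])
      h <- bn$y
      bn_cache <- bn[c("xhat", "istd")]
    }
    res_cache <- NULL
    r <- spec$stages$resolution[i]
    if (residual_enabled && r %in% spec$residual_stages) {
      up <- upscale2(a_prev, spec$residual_interp)
      P <- tn[[sprintf("res%d.P", r)]]
      d <- dim(up)
      proj <- array(P %*% matrix(up, d[1]), c(nrow(P), d[2], d[3], d[4]))
      h <- h + proj
      res_cache <- list(up = up)
    }
    act <- spec$stages$activation[i]
    a <- if (act == "tanh") tanh(h) else relu_fwd(h)
    if (keep_cache)
      cache[[i]] <- list(a_prev = a_prev, h = h, bn = bn_cache,
                         res = res_cache, a = a)
  }
  list(out = a, cache = cache)
}

# Backprop through the generator given d(loss)/d(output activation).
gen_backward <- function(fwd, g_out, params, spec, residual_enabled = TRUE) {
  tn <- params$tensors
  n <- nrow(spec$stages)
  grads <- list()
  g_a <- g_out
  for (i in n:1) {
    st <- fwd$cache[[i]]
    act <- spec$stages$activation[i]
    g_h <- if (act == "tanh") g_a * (1 - st$a^2) else g_a * (st$h > 0)
    r <- spec$stages$resolution[i]
    g_res_prev <- NULL
    if (!is.null(st$res)) {
      P <- tn[[sprintf("res%d.P", r)]]
      d <- dim(st$res$up)
      gm <- matrix(g_h, dim(g_h)[1])
      upm <- matrix(st$res$up, d[1])
      grads[[sprintf("res%d.P", r)]] <- gm %*% t(upm)
      g_up <- array(t(P) %*% gm, d)
      g_res_prev <- downsum2(g_up, spec$residual_interp)
    }
    if (spec$stages$batchnorm[i]) {
      bb <- bn_bwd(g_h, st$bn, tn[[sprintf("s%d.gamma", i)]])
      grads[[sprintf("s%d.gamma", i)]] <- bb$ggamma
      grads[[sprintf("s%d.beta", i)]] <- bb$gbeta
      g_h <- bb$gx
    }
    geom <- stage_geom(spec, i)
    bw <- cpp_convt_bwd(st$a_prev, dim(st$a_prev), tn[[sprintf("s%d.W", i)]],
                        g_h, geom$k, geom$s, geom$p)
    grads[[sprintf("s%d.W", i)]] <- bw$gW
    grads[[sprintf("s%d.b", i)]] <- as.numeric(bw$gb)
    g_a <- bw$gx
    if (!is.null(g_res_prev)) g_a <- g_a + g_res_prev
  }
  grads
}

# Discriminator forward on a (3,H,W,B) tensor in [-1,1]; returns
# probabilities and optionally the cache.
disc_forward <- function(x, params, spec, keep_cache = FALSE) {
  tn <- params$tensors
  n <- nrow(spec$stages)
  a <- x
  cache <- if (keep_cache) vector("list", n) else NULL
  for (i in seq_len(n)) {
    geom <- stage_geom(spec, i)
    a_prev <- a
    h <- cpp_conv_fwd(a_prev, dim(a_prev), tn[[sprintf("s%d.W", i)]],
                      tn[[sprintf("s%d.b", i)]], geom$k, geom$s, geom$p)
    bn_cache <- NULL
    if (spec$stages$batchnorm[i]) {
      bn <- bn_fwd(h, tn[[sprintf("s%d.gamma", i)]], tn[[sprintf("s%d.beta", i)]])
      h <- bn$y
      bn_cache <- bn[c("xhat", "istd")]
    }
    act <- spec$stages$activation[i]
    a <- if (act == "sigmoid") 1 / (1 + exp(-h)) else lrelu_fwd(h)
    if (keep_cache) cache[[i]] <- list(a_prev = a_prev, h = h, bn = bn_cache, a = a)
  }
  list(p = as.numeric(a), cache = cache)
}

# Backprop through the discriminator given d(loss)/d(probability).
# Returns parameter grads and the gradient wrt the input image tensor.
disc_backward <- function(fwd, g_p, params, spec) {
  tn <- params$tensors
  n <- nrow(spec$stages)
  grads <- list()
  p <- fwd$cache[[n]]$a
  g_a <- array(g_p, dim(p)) * p * (1 - p)   # through the sigmoid
  for (i in n:1) {
    st <- fwd$cache[[i]]
    g_h <- if (i == n) g_a else lrelu_bwd(g_a, st$h)
    if (spec$stages$batchnorm[i]) {
      bb <- bn_bwd(g_h, st$bn, tn[[sprintf("s%d.gamma", i)]])
      grads[[sprintf("s%d.gamma", i)]] <- bb$ggamma
      grads[[sprintf("s%d.beta", i)]] <- bb$gbeta
      g_h <- bb$gx
    }
    geom <- stage_geom(spec, i)
    bw <- cpp_conv_bwd(st$a_prev, dim(st$a_prev), tn[[sprintf("s%d.W", i)]],
                       g_h, geom$k, geom$s, geom$p)
    grads[[sprintf("s%d.W", i)]] <- bw$gW
    grads[[sprintf("s%d.b", i)]] <- as.numeric(bw$gb)
    g_a <- bw$gx
  }
  list(grads = grads, gx = g_a)
}

#' Run the generator on latent vectors
#'
#' @param z Latent vector (length `latent_dim`) or a `latent_dim x B` matrix.
#' @param params `net_params` for the generator spec.
#' @param spec Generator `gan_spec`.
#' @param residual_enabled Apply residual additions (only at stages listed in
#'   `spec$residual_stages`)? Scheduled off late in training.
#' @return `H x W x 3` array in \[-1, 1\] (or `H x W x 3 x B` for a batch).
#' @export
generator_forward <- function(z, params, spec, residual_enabled = TRUE) {
  stopifnot(inherits(spec, "gan_spec"), spec$role == "generator")
  if (is.vector(z)) z <- matrix(z, ncol = 1)
  if (nrow(z) != spec$latent_dim)
    stop("latent vector length must equal spec$latent_dim", call. = FALSE)
  out <- gen_forward(z, params, spec, residual_enabled)$out
  img <- aperm(out, c(2, 3, 1, 4))        # (H,W,3,B)
  if (dim(img)[4] == 1) img[, , , 1] else img
}

#' Score images with the discriminator
#'
#' @param img `H x W x 3` array (or `H x W x 3 x B`) with values in
#'   \[-1, 1\], or a `(3,H,W,B)` tensor.
#' @param params `net_params` for the discriminator spec.
#' @param spec Discriminator `gan_spec`.
#' @return Numeric vector of probabilities in (0, 1), one per image.
#' @export
discriminator_forward <- function(img, params, spec) {
  stopifnot(inherits(spec, "gan_spec"), spec$role == "discriminator")
  if (length(dim(img)) == 3) img <- array(img, c(dim(img), 1))
  if (dim(img)[3] == 3)       # H,W,3,B layout from the user
    img <- aperm(img, c(3, 1, 2, 4))
  if (dim(img)[2] != spec$resolution)
    stop("image resolution does not match the spec", call. = FALSE)
  disc_forward(img, params, spec)$p
}

#' Compute a residual feature stack for the next deconvolution stage
#'
#' Upscales stage-`i` feature maps by a factor of 2 (interpolation) and
#' projects their channels with a learned 1x1 convolution so the result can
#' be added elementwise to the pre-activation output of stage `i + 1`.
#'
#' @param features `H x W x C` feature-map stack of the source stage.
#' @param target_channels Channel count of the target stage.
#' @param projection `target_channels x C` matrix of 1x1 convolution
#'   weights.
#' @param method Upscale interpolation, `"nearest"` or `"bilinear"`.
#' @return `2H x 2W x target_channels` array.
#' @export
compute_residual <- function(features, target_channels, projection,
                             method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  if (length(dim(features)) != 3)
    stop("features must be an H x W x C array", call. = FALSE)
  cs <- dim(features)[3]
  if (!is.matrix(projection) || nrow(projection) != target_channels ||
      ncol(projection) != cs)
    stop("projection must be a target_channels x C matrix", call. = FALSE)
  x <- aperm(array(features, c(dim(features), 1)), c(3, 1, 2, 4))
  up <- upscale2(x, method)
  d <- dim(up)
  proj <- array(projection %*% matrix(up, d[1]),
                c(target_channels, d[2], d[3], 1))
  aperm(proj, c(2, 3, 1, 4))[, , , 1, drop = TRUE]
}
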