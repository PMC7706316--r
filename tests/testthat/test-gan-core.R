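# Architecture specs, forward passes, residual computation, and the
# correctness of the compiled convolution kernels (checked against finite
# differences through a smooth surrogate loss).

test_that("generator specs have the documented stage structure", {
  g128 <- build_generator_spec(128)
  g64 <- build_generator_spec(64)
  expect_equal(nrow(g128$stages), 6)
  expect_equal(nrow(g64$stages), 5)
  expect_equal(g128$stages$resolution, c(4, 8, 16, 32, 64, 128))
  expect_equal(g128$stages$out_channels, c(1024, 512, 256, 128, 64, 3))
  expect_equal(g128$residual_stages, c(16L, 32L, 64L, 128L))
  expect_equal(g128$stages$activation[6], "tanh")
  # stage count invariant for both networks
  for (res in c(16, 32, 64, 128)) {
    expect_equal(nrow(build_generator_spec(res)$stages), log2(res / 4) + 1)
    expect_equal(nrow(build_discriminator_spec(res)$stages), log2(res / 4) + 1)
  }
  expect_error(build_generator_spec(48), "power of two")
  expect_error(build_generator_spec(4), "power of two")
})

test_that("discriminator spec mirrors the generator and gates batch norm", {
  d128 <- build_discriminator_spec(128)
  d64 <- build_discriminator_spec(64)
  expect_equal(nrow(d128$stages), nrow(d64$stages) + 1)
  expect_false(any(build_discriminator_spec(64, use_batchnorm = FALSE)$stages$batchnorm))
  bn <- build_discriminator_spec(64, use_batchnorm = TRUE)$stages$batchnorm
  expect_false(bn[1])                    # first conv stage: no batch norm
  expect_false(bn[length(bn)])           # output stage: no batch norm
  expect_true(all(bn[2:(length(bn) - 1)]))
  gbn <- build_generator_spec(64, use_batchnorm = TRUE)$stages$batchnorm
  expect_false(gbn[length(gbn)])         # last deconv stage: no batch norm
  expect_true(all(gbn[-length(gbn)]))
})

test_that("generator and discriminator forward passes honour their contracts", {
  gs <- build_generator_spec(32, base_channels = 8, latent_dim = 20)
  ds <- build_discriminator_spec(32, base_channels = 8)
  pg <- init_net_params(gs, 1)
  pd <- init_net_params(ds, 2)
  set.seed(7)
  z <- matrix(rnorm(20 * 3), 20)
  img <- generator_forward(z, pg, gs)
  expect_identical(dim(img), c(32L, 32L, 3L, 3L))
  expect_true(all(img >= -1 & img <= 1))
  expect_identical(img, generator_forward(z, pg, gs))
  p <- discriminator_forward(img, pd, ds)
  expect_length(p, 3)
  expect_true(all(p > 0 & p < 1))
  # without batch norm, per-sample outputs ignore batch composition
  p1 <- discriminator_forward(img[, , , 1], pd, ds)
  expect_equal(p1, p[1], tolerance = 1e-12)
  expect_error(generator_forward(matrix(rnorm(6), 6), pg, gs), "latent")
  expect_error(discriminator_forward(array(0, c(16, 16, 3)), pd, ds), "resolution")
})

test_that("residual paths preserve shape and vanish with a zero projection", {
  for (res in c(64, 128)) {
    gs <- build_generator_spec(res, base_channels = 8)
    stages <- gs$stages
    for (i in 2:nrow(stages)) {
      s <- stages$resolution[i - 1]
      cs <- stages$out_channels[i - 1]
      ct <- stages$out_channels[i]
      f <- array(rnorm(s * s * cs), c(s, s, cs))
      P <- matrix(rnorm(ct * cs, 0, 0.1), ct, cs)
      r <- compute_residual(f, ct, P)
      expect_equal(dim(r), c(2 * s, 2 * s, ct))
      expect_true(all(compute_residual(f, ct, P * 0) == 0))
    }
  }
  # constant map under a column-identity projection stays constant
  f <- array(2, c(8, 8, 4))
  P <- matrix(0, 3, 4); P[, 1] <- 1
  for (method in c("nearest", "bilinear"))
    expect_true(all(compute_residual(f, 3, P, method) == 2))
  expect_error(compute_residual(f, 3, matrix(0, 2, 4)), "projection")
})

test_that("disabling residuals equals removing them from the spec", {
  gs <- build_generator_spec(32, base_channels = 8, latent_dim = 10)
  gs0 <- build_generator_spec(32, base_channels = 8, latent_dim = 10,
                              residual_stages = NULL)
  pg <- init_net_params(gs, 3)
  pg0 <- pg
  pg0$tensors <- pg$tensors[!grepl("^res", names(pg$tensors))]
  set.seed(1)
  z <- matrix(rnorm(10 * 2), 10)
  expect_equal(generator_forward(z, pg, gs, residual_enabled = FALSE),
               generator_forward(z, pg0, gs0))
})

test_that("compiled convolution kernels match finite differences", {
  set.seed(11)
  C <- 2; H <- 6; W <- 6; B <- 2; Cout <- 3; k <- 4L
  x <- array(rnorm(C * H * W * B), c(C, H, W, B))
  Wm <- matrix(rnorm(Cout * C * 16, 0, 0.2), Cout, C * 16)
  b <- rnorm(Cout)
  eps <- 1e-6
  ## strided convolution
  f <- function(x, Wm, b) sum(sin(tasselsynth:::cpp_conv_fwd(x, dim(x), Wm, b, k, 2L, 1L)))
  y <- tasselsynth:::cpp_conv_fwd(x, dim(x), Wm, b, k, 2L, 1L)
  bw <- tasselsynth:::cpp_conv_bwd(x, dim(x), Wm, cos(y), k, 2L, 1L)
  for (i in c(1, 17, 40)) {
    Wp <- Wm; Wp[i] <- Wm[i] + eps; Wn <- Wm; Wn[i] <- Wm[i] - eps
    expect_equal(bw$gW[i], (f(x, Wp, b) - f(x, Wn, b)) / (2 * eps), tolerance = 1e-5)
    xp <- x; xp[i] <- x[i] + eps; xn <- x; xn[i] <- x[i] - eps
    expect_equal(bw$gx[i], (f(xp, Wm, b) - f(xn, Wm, b)) / (2 * eps), tolerance = 1e-5)
  }
  bp <- b; bp[2] <- b[2] + eps; bn <- b; bn[2] <- b[2] - eps
  expect_equal(as.numeric(bw$gb)[2], (f(x, Wm, bp) - f(x, Wm, bn)) / (2 * eps),
               tolerance = 1e-5)
  ## transposed convolution
  Wt <- matrix(rnorm(C * Cout * 16, 0, 0.2), C, Cout * 16)
  bt <- rnorm(Cout)
  ft <- function(x, Wt, bt) sum(sin(tasselsynth:::cpp_convt_fwd(x, dim(x), Wt, bt, k, 2L, 1L)))
  yt <- tasselsynth:::cpp_convt_fwd(x, dim(x), Wt, bt, k, 2L, 1L)
  expect_equal(dim(yt), c(Cout, 2 * H, 2 * W, B))
  bwt <- tasselsynth:::cpp_convt_bwd(x, dim(x), Wt, cos(yt), k, 2L, 1L)
  for (i in c(2, 9, 30)) {
    Wp <- Wt; Wp[i] <- Wt[i] + eps; Wn <- Wt; Wn[i] <- Wt[i] - eps
    expect_equal(bwt$gW[i], (ft(x, Wp, bt) - ft(x, Wn, bt)) / (2 * eps), tolerance = 1e-5)
    xp <- x; xp[i] <- x[i] + eps; xn <- x; xn[i] <- x[i] - eps
    expect_equal(bwt$gx[i], (ft(xp, Wt, bt) - ft(xn, Wt, bt)) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("specs serialize to YAML and checkpoints bind to their spec", {
  gs <- build_generator_spec(64, base_channels = 16)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_gan_spec(gs, path)
  back <- read_gan_spec(path)
  expect_equal(back$stages, gs$stages)
  expect_equal(back$residual_stages, gs$residual_stages)
  expect_equal(back$latent_dim, gs$latent_dim)
  pg <- init_net_params(gs, 1)
  ck <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(pg, gs, ck)
  got <- load_checkpoint(ck, expected_spec = gs)
  expect_equal(got$params$tensors, pg$tensors)
  other <- build_generator_spec(32)
  expect_error(load_checkpoint(ck, expected_spec = other), "match")
})
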