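# Shared fixture builders for the test suite; everything is generated in
# code, nothing is read from disk.

tiny_tassel_set <- function(n, resolution = 32, seed0 = 1, n_branches = 5) {
  p <- tassel_params(resolution = resolution, n_branches = n_branches)
  lapply(seq_len(n), function(i) make_tassel_image(p, seed0 + i - 1))
}

tiny_sky_set <- function(n, resolution = 32, seed0 = 100) {
  p <- sky_params(resolution = resolution)
  lapply(seq_len(n), function(i) make_sky_image(p, seed0 + i - 1))
}

random_image8 <- function(h, w, seed) {
  set.seed(seed)
  array(as.numeric(sample(0:255, h * w * 3, replace = TRUE)), c(h, w, 3))
}

# Independent brute-force Otsu oracle: try all 256 thresholds, maximize
# between-class variance, smallest threshold wins ties.
otsu_brute_force <- function(channel) {
  v <- round(as.numeric(channel))
  best_t <- NA_integer_
  best_s <- -1
  n <- length(v)
  for (t in 0:255) {
    lower <- v <= t
    n0 <- sum(lower)
    n1 <- n - n0
    if (n0 == 0 || n1 == 0) s <- 0
    else {
      w0 <- n0 / n; w1 <- n1 / n
      s <- w0 * w1 * (mean(v[lower]) - mean(v[!lower]))^2
    }
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

# erode a binary mask by `r` pixels (used to test compose interiors)
erode_mask <- function(mask, r) {
  out <- mask
  H <- nrow(mask); W <- ncol(mask)
  for (dy in -r:r) for (dx in -r:r) {
    sh <- matrix(0, H, W)
    src_r <- pmin(pmax(seq_len(H) + dy, 1), H)
    src_c <- pmin(pmax(seq_len(W) + dx, 1), W)
    sh <- mask[src_r, src_c]
    out <- out * sh
  }
  out
}
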