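# Adversarial training: discriminator-first alternating updates with
# cross-entropy losses and Adam, a residual-enable schedule, per-epoch loss
# tracing, collapse detection and the batch-norm/residual ablation harness.

#' Training configuration
#'
#' @param learning_rate Adam step size (> 0). The full-scale recipes use
#'   1.5e-5 (tassel model, 2500 epochs) and 2e-5 (sky model, 600 epochs);
#'   desk-scale runs use DC-GAN's 2e-4.
#' @param epochs Number of passes over the dataset.
#' @param batch_size Mini-batch size (default 64).
#' @param residual_disable_epoch Epoch (0-based) at which residual additions
#'   switch off, or `NULL` to keep them throughout. The tassel recipe
#'   disables residuals after the first 40% of training (1000 of 2500
#'   epochs) because late residual addition introduces noise.
#' @param seed Integer seed covering weight init, shuffling and latent draws.
#' @param g_steps_per_d_step Generator updates per discriminator update
#'   (default 1).
#' @param beta1,beta2 Adam moment decay rates (DC-GAN's 0.5 and 0.999).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 2e-4, epochs = 10, batch_size = 64,
                         residual_disable_epoch = NULL, seed = 1,
                         g_steps_per_d_step = 1,
                         beta1 = 0.5, beta2 = 0.999) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (!is.null(residual_disable_epoch) && residual_disable_epoch > epochs)
    stop("residual_disable_epoch must be <= epochs", call. = FALSE)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 residual_disable_epoch = residual_disable_epoch,
                 seed = as.integer(seed),
                 g_steps_per_d_step = as.integer(g_steps_per_d_step),
                 beta1 = beta1, beta2 = beta2),
            class = "train_config")
}

#' Cross-entropy GAN losses
#'
#' Discriminator loss `-mean(log d_real) - mean(log(1 - d_fake))` and the
#' non-saturating generator loss `-mean(log d_fake)`. Probabilities are
#' clamped to `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param d_real Discriminator outputs on real images, in (0, 1).
#' @param d_fake Discriminator outputs on generated images.
#' @return List with `d_loss` and `g_loss`.
#' @export
gan_losses <- function(d_real, d_fake) {
  eps <- 1e-7
  pr <- clamp(d_real, eps, 1 - eps)
  pf <- clamp(d_fake, eps, 1 - eps)
  list(d_loss = -mean(log(pr)) - mean(log(1 - pf)),
       g_loss = -mean(log(pf)))
}

#' Residual-enable schedule
#'
#' Residual additions run for epochs `0 .. disable_epoch - 1` and are off
#' from `disable_epoch` on; `NULL` keeps them always on.
#'
#' @param epoch 0-based epoch index.
#' @param disable_epoch Cutoff epoch, or `NULL`.
#' @return Logical: residuals enabled at this epoch?
#' @export
residual_schedule <- function(epoch, disable_epoch = NULL) {
  if (epoch < 0) stop("epoch must be >= 0", call. = FALSE)
  is.null(disable_epoch) || epoch < disable_epoch
}

adam_init <- function(tensors) {
  list(m = lapply(tensors, function(t) t * 0),
       v = lapply(tensors, function(t) t * 0), t = 0L)
}

adam_step <- function(tensors, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    tensors[[nm]] <- tensors[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(tensors = tensors, state = state)
}

add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

# Stack a list of H x W x 3 images into a normalized (3,H,W,N) tensor.
stack_images <- function(images) {
  d <- dim(images[[1]])
  x <- array(0, c(3, d[1], d[2], length(images)))
  for (i in seq_along(images))
    x[, , , i] <- aperm(normalize_image(images[[i]]), c(3, 1, 2))
  x
}

#' Train the adversarial pair
#'
#' One discriminator update then `g_steps_per_d_step` generator updates per
#' mini-batch; the discriminator sees the real batch and freshly generated
#' images each step, and all randomness (weight init, shuffling, latent
#' draws) derives from `config$seed`, making runs bit-reproducible on one
#' machine.
#'
#' @param dataset Non-empty list of `ImageRGB` arrays at the spec resolution.
#' @param gen_spec,disc_spec Architecture specs from
#'   [build_generator_spec()] / [build_discriminator_spec()].
#' @param config A [train_config()].
#' @return List with `generator`, `discriminator` (`net_params`) and `trace`
#'   (a `loss_trace` data frame with per-epoch mean `d_loss`, `g_loss`).
#' @export
train_gan <- function(dataset, gen_spec, disc_spec, config = train_config()) {
  if (length(dataset) == 0) stop("dataset is empty", call. = FALSE)
  stopifnot(inherits(gen_spec, "gan_spec"), gen_spec$role == "generator",
            inherits(disc_spec, "gan_spec"), disc_spec$role == "discriminator")
  if (any(vapply(dataset, function(im) !all(dim(im)[1:2] == gen_spec$resolution),
                 logical(1))))
    stop("all images must match the spec resolution", call. = FALSE)
  x_all <- stack_images(dataset)
  n_img <- length(dataset)
  latent <- gen_spec$latent_dim
  with_seed(config$seed, {
    pg <- init_net_params(gen_spec, seed = sample.int(2^31 - 1, 1))
    pd <- init_net_params(disc_spec, seed = sample.int(2^31 - 1, 1))
    sg <- adam_init(pg$tensors)
    sd_ <- adam_init(pd$tensors)
    d_trace <- numeric(config$epochs)
    g_trace <- numeric(config$epochs)
    for (epoch in 0:(config$epochs - 1)) {
      res_on <- residual_schedule(epoch, config$residual_disable_epoch)
      idx <- sample.int(n_img)
      starts <- seq(1, n_img, by = config$batch_size)
      d_acc <- 0; g_acc <- 0
      for (s in starts) {
        take <- idx[s:min(s + config$batch_size - 1, n_img)]
        xb <- x_all[, , , take, drop = FALSE]
        B <- length(take)
        ## --- discriminator step ---
        z <- matrix(rnorm(latent * B), latent)
        fake <- gen_forward(z, pg, gen_spec, res_on)
        fr <- disc_forward(xb, pd, disc_spec, keep_cache = TRUE)
        ff <- disc_forward(fake$out, pd, disc_spec, keep_cache = TRUE)
        losses <- gan_losses(fr$p, ff$p)
        eps <- 1e-7
        g_real <- -1 / (B * clamp(fr$p, eps, 1 - eps))
        g_fake <- 1 / (B * (1 - clamp(ff$p, eps, 1 - eps)))
        gd <- add_grads(disc_backward(fr, g_real, pd, disc_spec)$grads,
                        disc_backward(ff, g_fake, pd, disc_spec)$grads)
        upd <- adam_step(pd$tensors, gd, sd_, config$learning_rate,
                         config$beta1, config$beta2)
        pd$tensors <- upd$tensors; sd_ <- upd$state
        ## --- generator step(s) ---
        g_loss_b <- NA_real_
        for (gs in seq_len(config$g_steps_per_d_step)) {
          z2 <- matrix(rnorm(latent * B), latent)
          fake2 <- gen_forward(z2, pg, gen_spec, res_on, keep_cache = TRUE)
          f2 <- disc_forward(fake2$out, pd, disc_spec, keep_cache = TRUE)
          g_loss_b <- -mean(log(clamp(f2$p, eps, 1 - eps)))
          g_p <- -1 / (B * clamp(f2$p, eps, 1 - eps))
          db <- disc_backward(f2, g_p, pd, disc_spec)
          gg <- gen_backward(fake2, db$gx, pg, gen_spec, res_on)
          updg <- adam_step(pg$tensors, gg, sg, config$learning_rate,
                            config$beta1, config$beta2)
          pg$tensors <- updg$tensors; sg <- updg$state
        }
        if (!is.finite(losses$d_loss) || !is.finite(g_loss_b))
          stop(sprintf("training aborted: non-finite loss at epoch %d", epoch),
               call. = FALSE)
        d_acc <- d_acc + losses$d_loss
        g_acc <- g_acc + g_loss_b
      }
      d_trace[epoch + 1] <- d_acc / length(starts)
      g_trace[epoch + 1] <- g_acc / length(starts)
    }
    trace <- structure(data.frame(epoch = 0:(config$epochs - 1),
                                  d_loss = d_trace, g_loss = g_trace),
                       class = c("loss_trace", "data.frame"))
    list(generator = pg, discriminator = pd, trace = trace)
  })
}

#' Detect early discriminator collapse in a loss trace
#'
#' Flags the failure mode where the discriminator loss drops to (near)
#' zero and stays there: true iff `d_loss < tol` for `window` consecutive
#' epochs.
#'
#' @param trace A `loss_trace` data frame (or numeric vector of d losses).
#' @param tol Loss threshold (default 0.01).
#' @param window Required consecutive epochs below `tol` (default 10).
#' @return Logical flag; attribute `"collapse_epoch"` holds the 0-based
#'   first epoch of the earliest qualifying window (or `NA`).
#' @export
detect_discriminator_collapse <- function(trace, tol = 0.01, window = 10) {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  d <- if (is.data.frame(trace)) trace$d_loss else as.numeric(trace)
  below <- d < tol
  r <- rle(below)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= window)
  if (length(hit) == 0)
    return(structure(FALSE, collapse_epoch = NA_integer_))
  first_start <- ends[hit[1]] - r$lengths[hit[1]] + 1L
  structure(TRUE, collapse_epoch = first_start - 1L)  # 0-based epoch
}

#' Run a batch-norm / residual ablation study
#'
#' Trains one model per variant on the same dataset under a common seed and
#' reports per-variant loss traces, collapse diagnostics and a few sample
#' generated images.
#'
#' @param dataset List of `ImageRGB` arrays.
#' @param resolution Model resolution (power of two).
#' @param variants List of lists with logical fields `batchnorm` and
#'   `residual`.
#' @param config A [train_config()] shared across variants.
#' @param base_channels Channel width passed to the spec builders.
#' @param collapse_tol,collapse_window Collapse-detector settings.
#' @param n_samples Generated samples kept per variant.
#' @return A `gan_ablation_report`: named list of variants, each with
#'   `trace`, `collapsed`, `collapse_epoch`, `min_d_loss`,
#'   `min_d_loss_epoch` and `samples`.
#' @export
run_ablation <- function(dataset, resolution, variants, config = train_config(),
                         base_channels = 64, collapse_tol = 0.01,
                         collapse_window = 10, n_samples = 4) {
  if (length(variants) == 0) stop("variants must be non-empty", call. = FALSE)
  out <- list()
  for (v in variants) {
    gen_spec <- build_generator_spec(
      resolution, use_batchnorm = isTRUE(v$batchnorm),
      residual_stages = if (isTRUE(v$residual)) c(16, 32, 64, 128) else NULL,
      base_channels = base_channels)
    disc_spec <- build_discriminator_spec(
      resolution, use_batchnorm = isTRUE(v$batchnorm),
      base_channels = base_channels)
    fit <- train_gan(dataset, gen_spec, disc_spec, config)
    col <- detect_discriminator_collapse(fit$trace, collapse_tol, collapse_window)
    z <- with_seed(config$seed, matrix(rnorm(gen_spec$latent_dim * n_samples),
                                       gen_spec$latent_dim))
    samples <- generator_forward(z, fit$generator, gen_spec,
                                 residual_enabled = residual_schedule(
                                   config$epochs - 1L,
                                   config$residual_disable_epoch))
    nm <- paste0(if (isTRUE(v$batchnorm)) "bn" else "nobn",
                 if (isTRUE(v$residual)) "_res" else "")
    out[[nm]] <- list(
      variant = v, trace = fit$trace,
      collapsed = as.logical(col),
      collapse_epoch = attr(col, "collapse_epoch"),
      min_d_loss = min(fit$trace$d_loss),
      min_d_loss_epoch = fit$trace$epoch[which.min(fit$trace$d_loss)],
      samples = denormalize_image(samples))
  }
  structure(out, class = "gan_ablation_report")
}
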