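# Evaluation suite: bounding-box morphometrics, SSIM pairing protocols,
# the KNN augmentation experiment, the inter-annotator error bound, and
# perceptual-test deck / confusion utilities.

#' Tight bounding box of the foreground
#'
#' RGB input is first reduced to its Y channel and Otsu-thresholded (the
#' brighter class is foreground); a binary mask is used directly.
#'
#' @param img_or_mask `ImageRGB` array or binary matrix.
#' @return A `bounding_box` list: `row_min`, `row_max`, `col_min`,
#'   `col_max` (1-based inclusive), `width`, `height`.
#' @export
bounding_box <- function(img_or_mask) {
  mask <- if (is.matrix(img_or_mask)) {
    assert_mask(img_or_mask, "img_or_mask")
    img_or_mask
  } else {
    extract_tassel_mask(img_or_mask)
  }
  if (sum(mask) == 0)
    stop("degenerate input: no foreground pixels", call. = FALSE)
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  structure(list(row_min = rows[1], row_max = rows[2],
                 col_min = cols[1], col_max = cols[2],
                 width = cols[2] - cols[1] + 1L,
                 height = rows[2] - rows[1] + 1L),
            class = "bounding_box")
}

#' Build a morphometrics table from image or mask sets
#'
#' @param training,generated Lists of `ImageRGB` arrays or binary masks.
#' @return A `MorphTable` data frame with `width`, `height`, `source`.
#' @export
morph_table <- function(training, generated) {
  one <- function(set, label) {
    boxes <- lapply(set, bounding_box)
    data.frame(width = vapply(boxes, `[[`, 0, "width"),
               height = vapply(boxes, `[[`, 0, "height"),
               source = label, stringsAsFactors = FALSE)
  }
  rbind(one(training, "training"), one(generated, "generated"))
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Summarize tassel widths and heights per source
#'
#' Means and population standard deviations (divide-by-N form) of widths
#' and heights, plus the fraction of tassels strictly wider than `cutoff`
#' pixels, per source.
#'
#' @param table A `MorphTable` data frame (`width`, `height`, `source`).
#' @param cutoff Width cutoff in pixels (default 60, the scale at which
#'   wide training tassels become rare at 128 resolution).
#' @return Data frame with one row per source.
#' @export
morph_stats <- function(table, cutoff = 60) {
  stopifnot(all(c("width", "height", "source") %in% names(table)))
  if (any(table$width < 0) || any(table$height < 0))
    stop("widths and heights must be non-negative", call. = FALSE)
  out <- do.call(rbind, lapply(split(table, table$source), function(d) {
    if (nrow(d) < 2)
      stop("need at least 2 rows per source", call. = FALSE)
    data.frame(source = d$source[1],
               n = nrow(d),
               width_mean = mean(d$width), width_sd = pop_sd(d$width),
               height_mean = mean(d$height), height_sd = pop_sd(d$height),
               frac_wider = mean(d$width > cutoff),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Structural similarity index between two images
#'
#' Single-scale SSIM on the 8-bit luma channel with the standard constants:
#' 11x11 Gaussian window (sigma 1.5), K1 = 0.01, K2 = 0.03, dynamic range
#' 255; the score is the mean of the SSIM map over the valid (fully
#' windowed) region. Identical images score exactly 1 and the metric is
#' symmetric.
#'
#' @param a,b `ImageRGB` arrays or single-channel matrices of equal size.
#' @return SSIM score in \[-1, 1\].
#' @export
ssim <- function(a, b) {
  ya <- luma8(a); yb <- luma8(b)
  if (!all(dim(ya) == dim(yb)))
    stop("images must have the same dimensions", call. = FALSE)
  win <- 11L
  if (any(dim(ya) < win))
    stop("images must be at least 11x11", call. = FALSE)
  g <- exp(-((-5:5)^2) / (2 * 1.5^2))
  w <- outer(g, g); w <- w / sum(w)
  # local weighted moments via explicit window shifts (valid region only)
  H <- nrow(ya); W <- ncol(ya)
  vh <- H - win + 1L; vw <- W - win + 1L
  mu_a <- matrix(0, vh, vw); mu_b <- matrix(0, vh, vw)
  s_aa <- matrix(0, vh, vw); s_bb <- matrix(0, vh, vw); s_ab <- matrix(0, vh, vw)
  for (i in seq_len(win)) {
    for (j in seq_len(win)) {
      wa <- ya[i:(i + vh - 1), j:(j + vw - 1)]
      wb <- yb[i:(i + vh - 1), j:(j + vw - 1)]
      wij <- w[i, j]
      mu_a <- mu_a + wij * wa
      mu_b <- mu_b + wij * wb
      s_aa <- s_aa + wij * wa * wa
      s_bb <- s_bb + wij * wb * wb
      s_ab <- s_ab + wij * wa * wb
    }
  }
  var_a <- s_aa - mu_a^2
  var_b <- s_bb - mu_b^2
  cov_ab <- s_ab - mu_a * mu_b
  C1 <- (0.01 * 255)^2
  C2 <- (0.03 * 255)^2
  map <- ((2 * mu_a * mu_b + C1) * (2 * cov_ab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2))
  mean(map)
}

#' Mean SSIM between randomly paired members of two sets
#'
#' For each repeat, every image of `setA` is paired with a uniformly drawn
#' partner from `setB` and the SSIM scores are averaged; the final score is
#' the mean over `n_repeats` repeats (default 3, the reporting protocol).
#'
#' @param setA,setB Non-empty lists of images.
#' @param n_repeats Number of pairing repeats.
#' @param seed Integer seed.
#' @return Mean SSIM score.
#' @export
paired_ssim_score <- function(setA, setB, n_repeats = 3, seed = 1) {
  if (length(setA) == 0 || length(setB) == 0)
    stop("sets must be non-empty", call. = FALSE)
  with_seed(seed, {
    reps <- vapply(seq_len(n_repeats), function(r) {
      partners <- sample.int(length(setB), length(setA), replace = TRUE)
      mean(vapply(seq_along(setA),
                  function(i) ssim(setA[[i]], setB[[partners[i]]]), 0))
    }, 0)
    mean(reps)
  })
}

#' Intraclass SSIM of a set
#'
#' Each image is compared against a randomly drawn partner from the same
#' set, excluding itself; averaged as in [paired_ssim_score()]. High values
#' indicate low variability across the set.
#'
#' @param set List of at least two images.
#' @param n_repeats Number of pairing repeats.
#' @param seed Integer seed.
#' @return Mean SSIM score (always <= 1).
#' @export
intraclass_ssim <- function(set, n_repeats = 3, seed = 1) {
  n <- length(set)
  if (n < 2) stop("set must contain at least 2 images", call. = FALSE)
  with_seed(seed, {
    reps <- vapply(seq_len(n_repeats), function(r) {
      mean(vapply(seq_len(n), function(i) {
        j <- sample((seq_len(n))[-i], 1)
        ssim(set[[i]], set[[j]])
      }, 0))
    }, 0)
    mean(reps)
  })
}

#' Lower bound on inter-annotator error
#'
#' For `K` annotators and `N` items, with `X(i, j)` the number of
#' annotators giving item `i` label `j`, the disagreement lower bound is
#' `e = (1 / (K N)) * sum_i min_j (K - X(i, j))`. Zero means unanimity on
#' every item; for binary labels the bound cannot exceed 0.5.
#'
#' @param m `N x K` matrix of categorical labels (one column per
#'   annotator).
#' @return Error bound `e` in \[0, 1\].
#' @export
interannotator_error <- function(m) {
  if (!is.matrix(m) || any(is.na(m)))
    stop("m must be a complete N x K matrix", call. = FALSE)
  K <- ncol(m)
  if (K < 2) stop("need at least 2 annotators", call. = FALSE)
  per_item <- apply(m, 1, function(row) K - max(table(row)))
  sum(per_item) / (K * nrow(m))
}

#' KNN data-augmentation experiment
#'
#' Splits the real data 50/50 into train and test halves (seeded,
#' stratified by class), then for each fraction `f` appends
#' `floor(f * n_train)` randomly drawn generated samples to the training
#' half and reports the test accuracy of a k-nearest-neighbour classifier
#' (Euclidean distance on the raw features, majority vote, k = 5 by
#' default).
#'
#' @param real_features,gen_features Numeric matrices (rows = samples;
#'   columns are tassel width and height in pixels).
#' @param real_labels,gen_labels Class label vectors (two classes).
#' @param fractions Append fractions, e.g. `c(0, 0.25, 0.5, 0.75)`.
#' @param k Number of neighbours (odd; default 5).
#' @param seed Integer seed for the split and the append draws.
#' @return Data frame with `fraction`, `n_appended`, `accuracy`.
#' @export
knn_augmentation_experiment <- function(real_features, real_labels,
                                        gen_features, gen_labels,
                                        fractions = c(0, 0.25, 0.5, 0.75),
                                        k = 5, seed = 1) {
  real_features <- as.matrix(real_features)
  gen_features <- as.matrix(gen_features)
  if (k %% 2 == 0) stop("k must be odd", call. = FALSE)
  real_labels <- as.factor(real_labels)
  gen_labels <- factor(gen_labels, levels = levels(real_labels))
  with_seed(seed, {
    ## stratified 50/50 split
    train_idx <- unlist(lapply(split(seq_along(real_labels), real_labels),
                               function(ix) sample(ix, floor(length(ix) / 2))))
    test_idx <- setdiff(seq_along(real_labels), train_idx)
    if (length(unique(real_labels[train_idx])) < 2 ||
        length(unique(real_labels[test_idx])) < 2)
      stop("a class is absent from one split half", call. = FALSE)
    n_train <- length(train_idx)
    rows <- lapply(fractions, function(f) {
      n_app <- floor(f * n_train)
      if (n_app > nrow(gen_features))
        stop("not enough generated samples to append", call. = FALSE)
      app <- if (n_app > 0) sample.int(nrow(gen_features), n_app) else integer(0)
      tr_x <- rbind(real_features[train_idx, , drop = FALSE],
                    gen_features[app, , drop = FALSE])
      tr_y <- c(real_labels[train_idx], gen_labels[app])
      pred <- class::knn(tr_x, real_features[test_idx, , drop = FALSE],
                         tr_y, k = k)
      data.frame(fraction = f, n_appended = n_app,
                 accuracy = mean(pred == real_labels[test_idx]))
    })
    do.call(rbind, rows)
  })
}

#' Build a shuffled perceptual-test deck with its answer key
#'
#' Concatenates real and generated images, shuffles them with a seeded
#' uniform permutation, and records the ground truth per deck position.
#'
#' @param real_images,generated_images Non-empty lists of images.
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, deck images are written
#'   as numbered PNG files with a `key.csv`.
#' @return List with `deck` (shuffled image list), `key` (factor
#'   `real`/`generated` per position) and `order` (the permutation).
#' @export
build_perception_deck <- function(real_images, generated_images, seed = 1,
                                  out_dir = NULL) {
  if (length(real_images) == 0 || length(generated_images) == 0)
    stop("both image lists must be non-empty", call. = FALSE)
  all_imgs <- c(real_images, generated_images)
  truth <- factor(rep(c("real", "generated"),
                      c(length(real_images), length(generated_images))),
                  levels = c("real", "generated"))
  ord <- with_seed(seed, sample.int(length(all_imgs)))
  deck <- all_imgs[ord]
  key <- truth[ord]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(deck))
      write_image(deck[[i]], file.path(out_dir, sprintf("item_%03d.png", i)))
    utils::write.csv(data.frame(item = seq_along(deck), truth = key),
                     file.path(out_dir, "key.csv"), row.names = FALSE)
  }
  list(deck = deck, key = key, order = ord)
}

#' Confusion table of perceptual responses, as column percentages
#'
#' Rows are perceived classes, columns true classes; each column is
#' normalized to sum to 100%.
#'
#' @param responses Vector of `"real"`/`"generated"` responses aligned with
#'   the key.
#' @param key Ground-truth factor from [build_perception_deck()].
#' @return 2 x 2 matrix of percentages (columns sum to 100).
#' @export
confusion_table <- function(responses, key) {
  if (length(responses) != length(key))
    stop("responses and key lengths differ", call. = FALSE)
  lev <- c("real", "generated")
  tab <- table(perceived = factor(responses, levels = lev),
               true = factor(key, levels = lev))
  sweep(tab, 2, pmax(colSums(tab), 1), "/") * 100
}
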