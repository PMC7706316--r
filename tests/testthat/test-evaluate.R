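# Evaluation suite: bounding boxes, morphometric summaries, SSIM protocols,
# the annotator-disagreement bound, KNN augmentation and perception decks.

test_that("bounding_box finds the tight foreground box", {
  m <- matrix(0, 128, 128)
  m[11:50, 21:40] <- 1
  bb <- bounding_box(m)
  expect_equal(bb$height, 40L)
  expect_equal(bb$width, 20L)
  full <- bounding_box(matrix(1, 16, 16))
  expect_equal(c(full$height, full$width), c(16L, 16L))
  single <- matrix(0, 10, 10); single[6, 8] <- 1
  bb1 <- bounding_box(single)
  expect_equal(c(bb1$width, bb1$height), c(1L, 1L))
  expect_error(bounding_box(matrix(0, 8, 8)), "degenerate")
  # brute-force agreement on random masks
  set.seed(4)
  for (i in 1:10) {
    mm <- matrix(rbinom(400, 1, 0.1), 20)
    if (sum(mm) == 0) mm[7, 9] <- 1
    bb <- bounding_box(mm)
    idx <- which(mm == 1, arr.ind = TRUE)
    expect_equal(c(bb$row_min, bb$row_max, bb$col_min, bb$col_max),
                 c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2])))
  }
})

test_that("morph_stats reports population deviations and width fractions", {
  tab <- data.frame(width = c(10, 10, 0, 10), height = c(5, 5, 8, 2),
                    source = c("training", "training", "generated", "generated"))
  st <- morph_stats(tab, cutoff = 6)
  tr <- st[st$source == "training", ]
  gen <- st[st$source == "generated", ]
  expect_equal(tr$width_sd, 0)
  expect_equal(gen$width_sd, 5)           # population form: sqrt(mean((x-mean)^2))
  expect_equal(gen$frac_wider, 0.5)       # strict inequality at the cutoff
  expect_error(morph_stats(data.frame(width = 1, height = 1, source = "x")),
               "at least 2")
  # fixture masks: stats match direct bounding-box computation
  p <- tassel_params(resolution = 32)
  masks <- lapply(1:5, function(s) make_tassel_mask(p, s))
  tab2 <- morph_table(masks, masks)
  widths <- vapply(masks, function(m) bounding_box(m)$width, 0)
  st2 <- morph_stats(tab2)
  expect_equal(st2$width_mean[st2$source == "training"], mean(widths))
})

test_that("ssim satisfies its limiting cases and symmetry", {
  img <- random_image8(32, 32, 1)
  expect_equal(ssim(img, img), 1)
  lo <- matrix(0, 16, 16); hi <- matrix(255, 16, 16)
  closed_form <- (0.01 * 255)^2 / (255^2 + (0.01 * 255)^2)
  expect_equal(ssim(lo, hi), closed_form, tolerance = 1e-6)
  for (s in 1:3) {
    a <- random_image8(24, 24, s)
    b <- random_image8(24, 24, s + 10)
    expect_equal(ssim(a, b), ssim(b, a))
  }
  expect_error(ssim(random_image8(16, 16, 1), random_image8(12, 12, 1)),
               "dimensions")
})

test_that("paired SSIM lies within the exhaustive pairwise range", {
  one <- list(random_image8(16, 16, 3))
  expect_equal(paired_ssim_score(one, one, seed = 1), 1)
  setA <- lapply(1:5, function(s) random_image8(16, 16, s))
  setB <- lapply(6:10, function(s) random_image8(16, 16, s))
  all_pairs <- outer(seq_along(setA), seq_along(setB),
                     Vectorize(function(i, j) ssim(setA[[i]], setB[[j]])))
  score <- paired_ssim_score(setA, setB, n_repeats = 3, seed = 7)
  expect_gte(score, min(all_pairs))
  expect_lte(score, max(all_pairs))
  expect_identical(score, paired_ssim_score(setA, setB, n_repeats = 3, seed = 7))
  expect_error(paired_ssim_score(list(), setB), "non-empty")
})

test_that("intraclass SSIM excludes self-pairing and is bounded by one", {
  copies <- replicate(4, random_image8(16, 16, 42), simplify = FALSE)
  expect_equal(intraclass_ssim(copies, seed = 1), 1)
  set <- lapply(1:6, function(s) random_image8(16, 16, s))
  v <- intraclass_ssim(set, seed = 2)
  expect_lte(v, 1)
  expect_identical(v, intraclass_ssim(set, seed = 2))
  expect_error(intraclass_ssim(set[1]), "at least 2")
})

test_that("interannotator_error evaluates the disagreement bound", {
  unanimous <- matrix(1L, 10, 4)
  expect_equal(interannotator_error(unanimous), 0)
  m <- rbind(c(1L, 1L, 1L), c(1L, 1L, 2L))   # votes (3,0) and (2,1)
  expect_equal(interannotator_error(m), 1 / 6)
  expect_equal(interannotator_error(matrix(c(1L, 2L), 1, 2)), 0.5)
  expect_error(interannotator_error(matrix(1L, 5, 1)), "annotators")
  # binary labels can never exceed the 0.5 bound
  set.seed(12)
  for (i in 1:100) {
    mm <- matrix(sample(1:2, 5 * 7, replace = TRUE), 7, 5)
    e <- interannotator_error(mm)
    expect_gte(e, 0)
    expect_lte(e, 0.5)
  }
})

test_that("knn augmentation is exact on well-separated clusters", {
  set.seed(5)
  n <- 40
  real_x <- rbind(cbind(rnorm(n, 0, 1), rnorm(n, 0, 1)),
                  cbind(rnorm(n, 10, 1), rnorm(n, 10, 1)))
  real_y <- rep(c("small", "wide"), each = n)
  gen_x <- rbind(cbind(rnorm(n, 0, 1), rnorm(n, 0, 1)),
                 cbind(rnorm(n, 10, 1), rnorm(n, 10, 1)))
  gen_y <- rep(c("small", "wide"), each = n)
  res <- knn_augmentation_experiment(real_x, real_y, gen_x, gen_y,
                                     fractions = c(0, 0.25, 0.5, 0.75), seed = 3)
  expect_equal(nrow(res), 4)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  expect_true(all(res$accuracy == 1))
  # the zero-fraction row is the unaugmented baseline
  base <- knn_augmentation_experiment(real_x, real_y, gen_x, gen_y,
                                      fractions = 0, seed = 3)
  expect_equal(res$accuracy[res$fraction == 0], base$accuracy)
  expect_error(knn_augmentation_experiment(real_x, real_y, gen_x, gen_y, k = 4),
               "odd")
})

test_that("perception decks shuffle with a key and tabulate responses", {
  real <- lapply(1:51, function(s) random_image8(8, 8, s))
  gen <- lapply(52:100, function(s) random_image8(8, 8, s))
  deck <- build_perception_deck(real, gen, seed = 4)
  expect_length(deck$deck, 100)
  expect_equal(as.numeric(table(deck$key)), c(51, 49))
  deck2 <- build_perception_deck(real, gen, seed = 4)
  expect_identical(deck$order, deck2$order)
  ## confusion summaries
  perfect <- confusion_table(as.character(deck$key), deck$key)
  expect_equal(unname(diag(perfect)), c(100, 100))
  expect_equal(unname(colSums(perfect)), c(100, 100), tolerance = 1e-9)
  all_real <- confusion_table(rep("real", 100), deck$key)
  expect_equal(unname(all_real["real", ]), c(100, 100))
  mixed <- confusion_table(sample(c("real", "generated"), 100, TRUE), deck$key)
  expect_equal(unname(colSums(mixed)), c(100, 100), tolerance = 1e-9)
  expect_error(confusion_table(rep("real", 99), deck$key), "length")
})
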