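test_that("stratified folds are disjoint, exhaustive, and balanced", {
  labels <- rep(c("positive", "negative"), c(2756, 2700))
  folds <- kfold_split(labels, k = 10, seed = 1)
  expect_length(folds, 10)
  all_idx <- sort(unlist(folds))
  expect_identical(all_idx, seq_along(labels))       # exhaustive, disjoint
  sizes <- lengths(folds)
  expect_lte(diff(range(sizes)), 1)
  expect_setequal(sizes, c(546, 545))
  expect_equal(sum(sizes == 546), 6)
  # stratification: each fold's class balance within one sample
  for (f in folds) {
    tab <- table(labels[f])
    expect_lte(abs(tab[["positive"]] - 276) , 1)
  }
  tiny <- kfold_split(rep(c("a", "b"), 10), k = 10, seed = 2)
  expect_true(all(lengths(tiny) == 2))
  expect_error(kfold_split(rep("a", 5), k = 10), "exceed")
  expect_identical(kfold_split(labels, 10, seed = 3),
                   kfold_split(labels, 10, seed = 3))
})

test_that("the gain-ratio tree separates and overfits as expected", {
  set.seed(20)
  n <- 300
  x <- rbind(matrix(rnorm(n * 2, 0), ncol = 2),
             matrix(rnorm(n * 2, 3), ncol = 2))
  y <- factor(rep(c("negative", "positive"), each = n))
  fit <- c45_fit(x, y)
  expect_gt(mean(predict(fit, x) == y), 0.95)
  probs <- predict(fit, x, type = "prob")
  expect_true(all(probs >= 0 & probs <= 1))
  # pure-noise labels: training accuracy exceeds held-out accuracy
  xn <- matrix(rnorm(400 * 5), ncol = 5)
  yn <- factor(rep(c("negative", "positive"), 200))
  fit_n <- c45_fit(xn[1:200, ], yn[1:200])
  expect_gt(mean(predict(fit_n, xn[1:200, ]) == yn[1:200]),
            mean(predict(fit_n, xn[201:400, ]) == yn[201:400]))
})

test_that("all four classifiers ace a linearly separable problem", {
  set.seed(21)
  n <- 120
  x <- rbind(matrix(rnorm(n * 4, 0), ncol = 4),
             matrix(rnorm(n * 4, 4), ncol = 4))
  colnames(x) <- paste0("Cz.f", 1:4)
  fm <- structure(list(
    x = x, label = factor(rep(c("negative", "positive"), each = n)),
    subject = rep("S01", 2 * n), clip = rep("c", 2 * n),
    feature_set = "synthetic", channels = "Cz"), class = "feature_matrix")
  for (kind in c("svm_linear", "dt_c45", "bpnn", "knn_brute")) {
    r <- evaluate_whole(classifier_spec(kind, seed = 4, inner_folds = 2), fm)
    expect_gte(r$test_acc, if (kind == "svm_linear") 0.99 else 0.95)
    expect_equal(r$scheme, "whole")
    expect_equal(nrow(r$folds), 10)
    expect_true(all(r$folds$test_acc >= 0 & r$folds$test_acc <= 1))
  }
})

test_that("deterministic classifiers reproduce exactly under a seed", {
  set.seed(22)
  x <- matrix(rnorm(200 * 3), ncol = 3)
  colnames(x) <- paste0("Cz.f", 1:3)
  fm <- structure(list(
    x = x, label = factor(rep(c("negative", "positive"), 100)),
    subject = rep("S01", 200), clip = rep("c", 200),
    feature_set = "synthetic", channels = "Cz"), class = "feature_matrix")
  for (kind in c("svm_linear", "dt_c45", "knn_brute")) {
    r1 <- evaluate_whole(classifier_spec(kind, seed = 5, inner_folds = 2), fm)
    r2 <- evaluate_whole(classifier_spec(kind, seed = 5, inner_folds = 2), fm)
    expect_identical(r1$folds, r2$folds)
  }
  b1 <- evaluate_whole(classifier_spec("bpnn", seed = 5), fm)
  b2 <- evaluate_whole(classifier_spec("bpnn", seed = 5), fm)
  expect_lt(abs(b1$test_acc - b2$test_acc), 0.02)
})

test_that("single-subject evaluation equals pooled; averaging is unweighted", {
  p <- subject_profile(effect_channels = c("Fp1", "Fp2"),
                       effect_bands = "gamma", effect_size = 3)
  eps <- make_epochs(p, 60, seed = 6)
  fm <- build_feature_matrix(eps, "de_gamma")
  spec <- classifier_spec("svm_linear", seed = 7, inner_folds = 2)
  w <- evaluate_whole(spec, fm)
  s <- evaluate_single(spec, fm)
  expect_equal(s$test_acc, w$test_acc, tolerance = 1e-12)

  # two subjects: reported accuracy is the unweighted mean (rows assigned
  # by parity so each pseudo-subject keeps both classes)
  fm2 <- fm
  fm2$subject <- ifelse(seq_len(nrow(fm$x)) %% 2 == 0, "S01", "S02")
  s2 <- evaluate_single(spec, fm2)
  expect_equal(s2$test_acc, mean(s2$per_subject$test_acc), tolerance = 1e-12)
  expect_equal(nrow(s2$per_subject), 2)

  # a subject with too few epochs is skipped with a warning
  fm3 <- fm
  fm3$subject[1:5] <- "S99"
  fm3$subject[6:nrow(fm$x)] <- "S01"
  expect_warning(s3 <- evaluate_single(spec, fm3), "skipped")
  expect_equal(nrow(s3$per_subject), 1)
})

test_that("label permutation keeps classifiers at chance (no leakage)", {
  p0 <- subject_profile(effect_size = 1)
  fm <- build_feature_matrix(make_epochs(p0, 150, seed = 8), "de_gamma")
  set.seed(23)
  fm$label <- factor(sample(rep(c("negative", "positive"), 150)),
                     levels = c("negative", "positive"))
  for (kind in c("dt_c45", "knn_brute")) {
    r <- evaluate_whole(classifier_spec(kind, seed = 9, inner_folds = 2), fm)
    expect_gt(r$test_acc, 0.38)
    expect_lt(r$test_acc, 0.62)
  }
})

test_that("subject-specific effects favor the per-subject scheme", {
  channel_sets <- list(c("Fp1", "Fp2"), c("T7", "T8"), c("O1", "O2"),
                       c("C3", "C4"))
  gap <- sapply(1:5, function(s) {
    eps <- list()
    for (si in 1:4) {
      p <- subject_profile(subject_id = sprintf("S%02d", si),
                           effect_channels = channel_sets[[si]],
                           effect_bands = "gamma", effect_size = 2.5)
      sub_eps <- make_epochs(p, 50, seed = s * 50 + si, clip_s = 25)
      sub_eps <- lapply(sub_eps, function(e) {
        e$subject_id <- p$subject_id
        e$clip_id <- paste0(p$subject_id, "_", e$clip_id)
        e
      })
      eps <- c(eps, sub_eps)
    }
    fm <- build_feature_matrix(eps, "de_gamma")
    spec <- classifier_spec("svm_linear", seed = s, inner_folds = 2)
    evaluate_single(spec, fm)$test_acc - evaluate_whole(spec, fm)$test_acc
  })
  expect_gte(median(gap), 0)
})
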