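#' Specify a classifier
#'
#' The four classifiers compared by the pipeline:
#' * `svm_linear` - linear-kernel SVM, cost C chosen by inner grid search;
#' * `dt_c45` - gain-ratio (C4.5-style) decision tree, see [c45_fit()];
#' * `bpnn` - single-hidden-layer back-propagation network with n input
#'   nodes (= feature count), l = 2 output nodes, and m hidden nodes from
#'   the node rule `m = round(sqrt(n * l))` unless overridden;
#' * `knn_brute` - exhaustive-search kNN with k chosen exhaustively from a
#'   grid by inner cross-validation.
#'
#' @param kind One of `"svm_linear"`, `"dt_c45"`, `"bpnn"`, `"knn_brute"`.
#' @param seed Integer seed controlling fold-internal randomness.
#' @param C_grid SVM cost grid.
#' @param k_grid kNN neighbor grid (odd values avoid ties).
#' @param hidden Override for the BPNN hidden-node count (NULL = node
#'   rule). `max_hidden` caps the rule, and `max_weights` bounds the total
#'   weight count: the BFGS optimizer behind the network fit scales
#'   quadratically with the number of weights, so very wide feature sets
#'   get a correspondingly narrow hidden layer.
#' @param maxit,decay BPNN training controls.
#' @param max_depth,min_split Decision-tree stops.
#' @param inner_folds Folds of the inner hyperparameter search.
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(kind = c("svm_linear", "dt_c45", "bpnn",
                                     "knn_brute"),
                            seed = 1,
                            C_grid = c(0.01, 0.1, 1, 10, 100),
                            k_grid = seq(1, 31, by = 2),
                            hidden = NULL, max_hidden = 24,
                            max_weights = 2000,
                            maxit = 120, decay = 5e-4,
                            max_depth = 12, min_split = 10,
                            inner_folds = 3) {
  kind <- match.arg(kind)
  if (kind == "svm_linear" && length(C_grid) == 0) stop("empty C grid")
  if (kind == "knn_brute" && length(k_grid) == 0) stop("empty k grid")
  structure(list(kind = kind, seed = seed, C_grid = C_grid, k_grid = k_grid,
                 hidden = hidden, max_hidden = max_hidden,
                 max_weights = max_weights, maxit = maxit,
                 decay = decay, max_depth = max_depth,
                 min_split = min_split, inner_folds = inner_folds),
            class = "classifier_spec")
}

#' Stratified k-fold partition
#'
#' Splits indices into k disjoint, exhaustive folds stratified by class,
#' with total fold sizes differing by at most 1 (per-class remainders are
#' assigned greedily to the currently smallest folds). Deterministic for a
#' given seed.
#'
#' @param labels Class label vector (length = number of samples).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return List of k integer index vectors.
#' @export
kfold_split <- function(labels, k = 10, seed = 1) {
  n <- length(labels)
  if (k > n) stop("k must not exceed the number of samples")
  folds <- vector("list", k)
  sizes <- integer(k)
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      n_c <- length(idx)
      base <- n_c %/% k
      extras <- n_c %% k
      alloc <- rep(base, k)
      if (extras > 0) {
        # give remainders to the folds that are currently smallest
        ord <- order(sizes, seq_len(k))
        alloc[ord[seq_len(extras)]] <- base + 1L
      }
      stops <- cumsum(alloc)
      starts <- c(1L, stops[-k] + 1L)
      for (f in seq_len(k)) {
        if (alloc[f] > 0)
          folds[[f]] <- c(folds[[f]], idx[starts[f]:stops[f]])
      }
      sizes <- sizes + alloc
    }
  })
  lapply(folds, sort)
}

accuracy <- function(truth, pred) mean(truth == pred)

# ---- per-classifier fit/predict -------------------------------------------

fit_model <- function(spec, x, y, hyper, seed, fast = FALSE) {
  switch(spec$kind,
    # inner-search fits only rank hyperparameters, so they may run at a
    # looser KKT tolerance than the final model
    svm_linear = e1071::svm(x, y, kernel = "linear", cost = hyper,
                            scale = apply(x, 2, stats::sd) > 0,
                            tolerance = if (fast) 0.01 else 0.001),
    dt_c45 = c45_fit(x, y, max_depth = spec$max_depth,
                     min_split = spec$min_split),
    bpnn = {
      n_in <- ncol(x)
      m <- if (!is.null(spec$hidden)) spec$hidden
           else max(1L, min(spec$max_hidden, round(sqrt(n_in * 2)),
                            (spec$max_weights - 2L) %/% (n_in + 3L)))
      with_seed(seed, {
        nnet::nnet(x, nnet::class.ind(y), size = m, softmax = TRUE,
                   maxit = spec$maxit, decay = spec$decay, trace = FALSE,
                   MaxNWts = (n_in + 1) * m + (m + 1) * 2 + 10)
      })
    },
    knn_brute = list(x = x, y = y,
                     k = min(hyper, nrow(x) - 1)))  # lazy learner
}

predict_model <- function(spec, model, x, levels) {
  switch(spec$kind,
    svm_linear = stats::predict(model, x),
    dt_c45 = stats::predict(model, x),
    bpnn = {
      p <- stats::predict(model, x)
      factor(colnames(p)[max.col(p, ties.method = "first")],
             levels = levels)
    },
    knn_brute = class::knn(model$x, x, model$y, k = model$k))
}

# Inner hyperparameter search (SVM cost / kNN k) by stratified inner CV on
# the training rows only; other classifiers have no searched parameter.
# For large training folds the search runs on a stratified subsample of
# `search_cap` rows (the final fit always uses every training row); ties
# resolve to the first (most regularized) grid value.
select_hyper <- function(spec, x, y, seed, search_cap = 800) {
  grid <- switch(spec$kind, svm_linear = spec$C_grid,
                 knn_brute = spec$k_grid, return(NULL))
  if (length(grid) == 1) return(grid[1])
  if (length(y) > search_cap) {
    sub <- with_seed(child_seed(seed, 77L), {
      unlist(lapply(levels(y), function(lv) {
        idx <- which(y == lv)
        sample(idx, round(search_cap * length(idx) / length(y)))
      }))
    })
    x <- x[sub, , drop = FALSE]
    y <- droplevels(y[sub])
  }
  k_inner <- min(spec$inner_folds, min(table(y)))
  inner <- kfold_split(y, k = k_inner, seed = seed)
  if (spec$kind == "knn_brute") {
    # k cannot exceed the inner training-fold size
    n_tr_min <- length(y) - max(lengths(inner))
    grid <- grid[grid <= max(1, n_tr_min - 1)]
    if (length(grid) == 0) grid <- 1
    if (length(grid) == 1) return(grid[1])
  }
  scores <- vapply(grid, function(h) {
    mean(vapply(seq_along(inner), function(f) {
      te <- inner[[f]]
      tr <- setdiff(seq_along(y), te)
      m <- fit_model(spec, x[tr, , drop = FALSE], y[tr], h, seed,
                     fast = TRUE)
      accuracy(y[te], predict_model(spec, m, x[te, , drop = FALSE],
                                    levels(y)))
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(scores)]
}

#' Cross-validated training and scoring of one classifier
#'
#' For each fold the model is fitted on the other folds - including any
#' normalization statistics and hyperparameter search, computed strictly
#' inside the training rows - and scored on both the training and the held
#' out rows.
#'
#' @param spec A [classifier_spec()].
#' @param fm A `feature_matrix`.
#' @param folds Fold index list from [kfold_split()] (default: 10 folds).
#' @param normalize Column normalization fitted per training fold:
#'   `"none"`, `"zscore"`, or `"minmax01"`.
#' @param k Number of folds when `folds` is NULL.
#' @return A `cv_result`: per-fold accuracies plus their means.
#' @export
train_and_score <- function(spec, fm, folds = NULL,
                            normalize = "none", k = 10) {
  y <- droplevels(fm$label)
  if (nlevels(y) < 2) stop("need two classes")
  if (is.null(folds)) folds <- kfold_split(y, k = k, seed = spec$seed)
  res <- lapply(seq_along(folds), function(f) {
    te <- folds[[f]]
    tr <- setdiff(seq_len(nrow(fm$x)), te)
    if (nlevels(droplevels(y[tr])) < 2)
      stop("fold ", f, " leaves a single-class training set")
    norm <- normalize_fit(fm$x[tr, , drop = FALSE], normalize)
    xtr <- normalize_apply(fm$x[tr, , drop = FALSE], norm)
    xte <- normalize_apply(fm$x[te, , drop = FALSE], norm)
    fold_seed <- child_seed(spec$seed, f)
    hyper <- select_hyper(spec, xtr, y[tr], fold_seed)
    model <- fit_model(spec, xtr, y[tr], hyper, fold_seed)
    pr_tr <- predict_model(spec, model, xtr, levels(y))
    pr_te <- predict_model(spec, model, xte, levels(y))
    data.frame(fold = f,
               train_acc = accuracy(y[tr], pr_tr),
               test_acc = accuracy(y[te], pr_te),
               recall_neg = mean(pr_te[y[te] == levels(y)[1]] ==
                                   levels(y)[1]),
               recall_pos = mean(pr_te[y[te] == levels(y)[2]] ==
                                   levels(y)[2]),
               hyper = if (is.null(hyper)) NA_real_ else hyper)
  })
  folds_df <- do.call(rbind, res)
  structure(list(classifier = spec$kind, scheme = NA_character_,
                 feature_set = fm$feature_set,
                 electrode_scheme = NA_character_,
                 folds = folds_df,
                 train_acc = mean(folds_df$train_acc),
                 test_acc = mean(folds_df$test_acc)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s [%s/%s]: train %.4f  test %.4f (%d folds)\n",
              x$classifier, x$scheme, x$feature_set,
              x$train_acc, x$test_acc, nrow(x$folds)))
  invisible(x)
}

#' Pooled ("whole") cross-validated evaluation
#'
#' All subjects' epochs are pooled into a single stratified k-fold
#' cross-validation.
#'
#' @inheritParams train_and_score
#' @export
evaluate_whole <- function(spec, fm, normalize = "none", k = 10) {
  out <- train_and_score(spec, fm, normalize = normalize, k = k)
  out$scheme <- "whole"
  out
}

#' Per-subject ("single") cross-validated evaluation
#'
#' Each subject is cross-validated separately and the reported accuracy is
#' the unweighted mean across subjects. Subjects with fewer than k epochs
#' (or a single class) are skipped with a warning.
#'
#' @inheritParams train_and_score
#' @export
evaluate_single <- function(spec, fm, normalize = "none", k = 10) {
  subjects <- unique(fm$subject)
  per_subject <- list()
  for (s in subjects) {
    idx <- which(fm$subject == s)
    ys <- droplevels(fm$label[idx])
    if (length(idx) < k || nlevels(ys) < 2) {
      warning("subject ", s, " skipped (too few epochs or single class)")
      next
    }
    sub_fm <- fm
    sub_fm$x <- fm$x[idx, , drop = FALSE]
    sub_fm$label <- fm$label[idx]
    sub_fm$subject <- fm$subject[idx]
    sub_fm$clip <- fm$clip[idx]
    r <- train_and_score(spec, sub_fm, normalize = normalize, k = k)
    r$folds$subject <- s
    per_subject[[s]] <- r
  }
  if (length(per_subject) == 0) stop("no subject had enough epochs")
  folds_df <- do.call(rbind, lapply(per_subject, function(r) r$folds))
  structure(list(classifier = spec$kind, scheme = "single",
                 feature_set = fm$feature_set,
                 electrode_scheme = NA_character_,
                 folds = folds_df,
                 per_subject = data.frame(
                   subject = names(per_subject),
                   train_acc = vapply(per_subject, function(r) r$train_acc,
                                      numeric(1)),
                   test_acc = vapply(per_subject, function(r) r$test_acc,
                                     numeric(1))),
                 train_acc = mean(vapply(per_subject,
                                         function(r) r$train_acc,
                                         numeric(1))),
                 test_acc = mean(vapply(per_subject,
                                        function(r) r$test_acc,
                                        numeric(1)))),
            class = "cv_result")
}
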