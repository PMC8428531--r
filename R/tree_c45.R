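# C4.5-style decision tree: axis-aligned numeric splits chosen by the
# information gain ratio (gain divided by the split information), the
# criterion that distinguishes C4.5 from CART's Gini. Grown recursively
# with depth / minimum-node-size stopping; no pruning beyond the stops.

grow_c45 <- function(x, y01, depth, max_depth, min_split, min_leaf) {
  n <- length(y01)
  pos <- sum(y01)
  node <- list(n = n, prob_pos = pos / n)
  if (depth >= max_depth || n < min_split || pos == 0 || pos == n) {
    node$leaf <- TRUE
    return(node)
  }
  best <- .best_split_cpp(x, y01, as.integer(min_leaf))
  if (best[1] == 0 || best[4] <= 1e-12) {
    node$leaf <- TRUE
    return(node)
  }
  best_j <- as.integer(best[1])
  left <- x[, best_j] <= best[2]
  node$leaf <- FALSE
  node$feature <- best_j
  node$threshold <- best[2]
  node$left <- grow_c45(x[left, , drop = FALSE], y01[left],
                        depth + 1, max_depth, min_split, min_leaf)
  node$right <- grow_c45(x[!left, , drop = FALSE], y01[!left],
                         depth + 1, max_depth, min_split, min_leaf)
  node
}

#' Fit a C4.5-style gain-ratio decision tree
#'
#' Binary classifier with numeric features; each split maximizes the
#' information gain ratio among splits with at least the average gain (the
#' C4.5 eligibility guard against bias toward uninformative splits).
#'
#' @param x Numeric matrix (rows = samples).
#' @param y Factor with two levels.
#' @param max_depth Maximum tree depth (default 12).
#' @param min_split Minimum node size to attempt a split (default 10).
#' @param min_leaf Minimum samples per child (default 3).
#' @return A `c45_tree` model object.
#' @export
c45_fit <- function(x, y, max_depth = 12, min_split = 10, min_leaf = 3) {
  stopifnot(is.factor(y), nlevels(y) == 2, nrow(x) == length(y))
  y01 <- as.integer(y) - 1L
  root <- grow_c45(as.matrix(x), y01, 0L, max_depth, min_split, min_leaf)
  structure(list(root = root, levels = levels(y)), class = "c45_tree")
}

predict_node <- function(node, xrow) {
  while (!node$leaf) {
    node <- if (xrow[node$feature] <= node$threshold) node$left
            else node$right
  }
  node$prob_pos
}

#' Predict with a [c45_fit()] tree
#' @param object A `c45_tree`.
#' @param newdata Numeric matrix.
#' @param type `"class"` or `"prob"` (probability of the second level).
#' @param ... Unused.
#' @export
predict.c45_tree <- function(object, newdata, type = c("class", "prob"),
                             ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  p <- apply(newdata, 1, function(r) predict_node(object$root, r))
  if (type == "prob") return(p)
  factor(object$levels[1L + as.integer(p > 0.5)], levels = object$levels)
}
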