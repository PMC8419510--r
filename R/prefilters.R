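# Filter-style feature reduction applied before the wrapper search:
# impurity-decrease (Gini) importance aggregated over a tree ensemble, and a
# chi-square dependency score between discretized features and the class
# label. Both are ranking scores only; no p-value calibration.

#' Build a decision-tree node
#'
#' Minimal tree representation consumed by the importance formulas. A node is
#' either internal (both children and a `split_feature`) or a leaf (neither).
#'
#' @param weighted_samples Nonnegative weight (typically the sample count)
#'   reaching the node.
#' @param impurity Gini impurity of the node's class distribution.
#' @param split_feature 1-based index of the splitting feature, or `NULL` for
#'   a leaf.
#' @param left,right Child nodes, or `NULL` for a leaf.
#' @param threshold Optional numeric split threshold (kept for prediction /
#'   inspection; unused by the importance formulas).
#' @return An object of class `who_tree_node`.
#' @export
tree_node <- function(weighted_samples, impurity, split_feature = NULL,
                      left = NULL, right = NULL, threshold = NULL) {
  if (weighted_samples < 0) stop("weighted_samples must be nonnegative")
  if (impurity < 0) stop("impurity must be nonnegative")
  internal <- !is.null(split_feature)
  if (internal && (is.null(left) || is.null(right))) {
    stop("an internal node needs both children")
  }
  if (!internal && (!is.null(left) || !is.null(right))) {
    stop("a leaf must not have children")
  }
  structure(
    list(
      weighted_samples = as.numeric(weighted_samples),
      impurity = as.numeric(impurity),
      split_feature = if (internal) as.integer(split_feature) else NULL,
      threshold = threshold,
      left = left, right = right
    ),
    class = "who_tree_node"
  )
}

#' Wrap a root node as a decision tree
#'
#' @param root A `who_tree_node`.
#' @param n_features Number of features the tree's split indices refer to.
#' @return An object of class `who_tree`.
#' @export
decision_tree <- function(root, n_features) {
  n_features <- as.integer(n_features)
  if (n_features < 1L) stop("n_features must be positive")
  check <- function(node) {
    if (is.null(node$split_feature)) return(invisible(NULL))
    if (node$split_feature > n_features) {
      stop("split_feature exceeds n_features")
    }
    check(node$left); check(node$right)
  }
  check(root)
  structure(list(root = root, n_features = n_features), class = "who_tree")
}

.is_leaf <- function(node) is.null(node$split_feature)

#' Impurity decrease of a single split
#'
#' The importance of an internal node k is the weighted impurity it removes:
#' `w_k C_k - w_left C_left - w_right C_right`, where `w` is the weighted
#' sample count reaching the node and `C` its Gini impurity.
#'
#' @param node An internal `who_tree_node`.
#' @return The (possibly negative only through numeric noise) impurity
#'   decrease of the split.
#' @examples
#' stump <- tree_node(10, 0.5, split_feature = 1,
#'                    left = tree_node(6, 0.2), right = tree_node(4, 0.3))
#' node_importance(stump)  # 2.6
#' @export
node_importance <- function(node) {
  if (.is_leaf(node)) stop("node_importance is defined for internal nodes only")
  node$weighted_samples * node$impurity -
    node$left$weighted_samples * node$left$impurity -
    node$right$weighted_samples * node$right$impurity
}

# Collect (feature, importance) pairs over all internal nodes of a tree.
.internal_importances <- function(node, acc) {
  if (.is_leaf(node)) return(acc)
  acc[[length(acc) + 1L]] <- c(node$split_feature, node_importance(node))
  acc <- .internal_importances(node$left, acc)
  .internal_importances(node$right, acc)
}

#' Per-tree feature importance
#'
#' For one tree, the raw importance of feature i is the sum of the impurity
#' decreases of the nodes splitting on i, divided by the total impurity
#' decrease over all internal nodes; the normalized importance rescales the
#' raw values to sum to 1.
#'
#' @param tree A `who_tree`.
#' @return A list of class `importance_vector` with `raw` and `normalized`
#'   numeric vectors of length `n_features`.
#' @export
tree_feature_importance <- function(tree) {
  stopifnot(inherits(tree, "who_tree"))
  pairs <- .internal_importances(tree$root, list())
  if (length(pairs) == 0L) stop("tree has no internal nodes")
  node_imp <- vapply(pairs, `[`, numeric(1), 2L)
  feat <- vapply(pairs, `[`, numeric(1), 1L)
  total <- sum(node_imp)
  raw <- numeric(tree$n_features)
  for (k in seq_along(feat)) {
    raw[feat[k]] <- raw[feat[k]] + node_imp[k]
  }
  if (total != 0) raw <- raw / total
  s <- sum(raw)
  normalized <- if (s != 0) raw / s else raw
  structure(list(raw = raw, normalized = normalized), class = "importance_vector")
}

#' Forest-averaged feature importance
#'
#' Averages the normalized per-tree importances over an ensemble: the
#' importance of feature i is the mean over trees of its normalized per-tree
#' importance.
#'
#' @param trees A list of `who_tree` objects with a common `n_features`.
#' @return A list of class `importance_vector` with `forest_averaged` (length
#'   `n_features`) and `n_trees`.
#' @export
forest_feature_importance <- function(trees) {
  if (length(trees) < 1L) stop("forest_feature_importance needs >= 1 tree")
  p <- trees[[1L]]$n_features
  if (!all(vapply(trees, function(t) t$n_features, integer(1)) == p)) {
    stop("all trees must have the same n_features")
  }
  acc <- numeric(p)
  for (t in trees) {
    acc <- acc + tree_feature_importance(t)$normalized
  }
  structure(
    list(forest_averaged = acc / length(trees), n_trees = length(trees)),
    class = "importance_vector"
  )
}

.gini <- function(y) {
  n <- length(y)
  if (n == 0L) return(0)
  p1 <- sum(y) / n
  1 - p1^2 - (1 - p1)^2
}

# Best threshold split of one feature, vectorized over all cut points.
# Returns c(decrease, threshold) or NULL when no valid split exists.
.best_split_feature <- function(x, y, w_c) {
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  n <- length(xs)
  cuts <- which(xs[-n] < xs[-1L])  # split between i and i+1
  if (length(cuts) == 0L) return(NULL)
  cum1 <- cumsum(ys)
  nl <- cuts
  n1l <- cum1[cuts]
  nr <- n - nl
  n1r <- cum1[n] - n1l
  gini_l <- 1 - (n1l / nl)^2 - ((nl - n1l) / nl)^2
  gini_r <- 1 - (n1r / nr)^2 - ((nr - n1r) / nr)^2
  decrease <- n * w_c - nl * gini_l - nr * gini_r
  k <- which.max(decrease)
  c(decrease[k], (xs[cuts[k]] + xs[cuts[k] + 1L]) / 2)
}

.grow_node <- function(x, y, depth, max_depth, min_split, mtry) {
  n <- length(y)
  imp <- .gini(y)
  leaf <- function() tree_node(n, imp)
  if (depth >= max_depth || n < min_split || imp == 0) return(leaf())
  p <- ncol(x)
  feats <- if (mtry < p) sort(sample.int(p, mtry)) else seq_len(p)
  best <- NULL
  for (j in feats) {
    sp <- .best_split_feature(x[, j], y, imp)
    if (!is.null(sp) && sp[1L] > 1e-12 && (is.null(best) || sp[1L] > best$dec)) {
      best <- list(dec = sp[1L], feature = j, threshold = sp[2L])
    }
  }
  if (is.null(best)) return(leaf())
  go_left <- x[, best$feature] <= best$threshold
  tree_node(
    n, imp, split_feature = best$feature, threshold = best$threshold,
    left = .grow_node(x[go_left, , drop = FALSE], y[go_left],
                      depth + 1L, max_depth, min_split, mtry),
    right = .grow_node(x[!go_left, , drop = FALSE], y[!go_left],
                       depth + 1L, max_depth, min_split, mtry)
  )
}

#' Grow a CART-style classification tree
#'
#' Greedy binary splits minimizing Gini impurity, with a depth limit. Used by
#' [grow_forest()]; exposed for tests and inspection.
#'
#' @param x Numeric matrix (samples x features).
#' @param y Binary (0/1) label vector.
#' @param max_depth Maximum tree depth (root at depth 0).
#' @param min_split Minimum samples required to attempt a split.
#' @param mtry Number of features considered per split (`NULL` = all).
#' @return A `who_tree`.
#' @export
grow_tree <- function(x, y, max_depth = 5L, min_split = 2L, mtry = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (is.null(mtry)) mtry <- ncol(x)
  decision_tree(.grow_node(x, y, 0L, max_depth, min_split, mtry), ncol(x))
}

#' Grow a bootstrap ensemble of Gini trees
#'
#' Bagged CART trees (bootstrap rows, random feature subsets per split) whose
#' normalized importances feed [forest_feature_importance()].
#'
#' @inheritParams grow_tree
#' @param n_trees Ensemble size. Default 50.
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @param seed Integer seed; the grower draws through an isolated RNG stream.
#' @return A list of `who_tree` objects.
#' @export
grow_forest <- function(x, y, n_trees = 50L, max_depth = 5L, min_split = 2L,
                        mtry = NULL, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  with_local_seed(seed, {
    lapply(seq_len(n_trees), function(t) {
      idx <- sample.int(nrow(x), nrow(x), replace = TRUE)
      grow_tree(x[idx, , drop = FALSE], y[idx], max_depth = max_depth,
                min_split = min_split, mtry = mtry)
    })
  })
}

#' Gini importance of each feature via a bagged tree ensemble
#'
#' Convenience wrapper: grows a forest on `(x, y)` and returns the
#' forest-averaged normalized importances. Trees in which no split was found
#' (degenerate bootstrap samples) are dropped from the average.
#'
#' @inheritParams grow_forest
#' @return Numeric vector of per-feature importances (sums to 1 when any
#'   split occurred).
#' @export
gini_feature_scores <- function(x, y, n_trees = 50L, max_depth = 5L,
                                mtry = NULL, seed = 1L) {
  trees <- grow_forest(x, y, n_trees = n_trees, max_depth = max_depth,
                       mtry = mtry, seed = seed)
  usable <- Filter(function(t) !.is_leaf(t$root), trees)
  if (length(usable) == 0L) {
    warning("no tree found any split; importances are all zero")
    return(numeric(ncol(as.matrix(x))))
  }
  forest_feature_importance(usable)$forest_averaged
}

#' Chi-square statistic between observed and expected counts
#'
#' The plain Pearson statistic `sum_j (Y_j - E_j)^2 / E_j` over cells, with
#' no continuity correction.
#'
#' @param observed Nonnegative numeric vector of observed counts `Y_j`.
#' @param expected Positive numeric vector of expected counts `E_j`.
#' @return A list of class `chi_square_score`: `statistic`, `observed`,
#'   `expected`, `n_cells`.
#' @examples
#' chi_square_score(c(10, 20), c(15, 15))$statistic  # 10/3
#' @export
chi_square_score <- function(observed, expected) {
  observed <- as.numeric(observed)
  expected <- as.numeric(expected)
  if (length(observed) != length(expected)) {
    stop("observed and expected must have equal length")
  }
  if (any(expected <= 0)) stop("all expected counts must be > 0")
  if (any(observed < 0)) stop("observed counts must be nonnegative")
  structure(
    list(
      statistic = sum((observed - expected)^2 / expected),
      observed = observed, expected = expected,
      n_cells = length(observed)
    ),
    class = "chi_square_score"
  )
}

# Equal-frequency discretization; collapses duplicated quantile breaks.
.discretize <- function(v, bins) {
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1L),
                               names = FALSE, type = 7))
  if (length(br) < 3L) return(NULL)  # effectively constant: < 2 bins
  cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Chi-square dependency score of each feature with the class label
#'
#' Each feature is discretized into (up to) `bins` equal-frequency bins; the
#' statistic of the bin-by-class contingency table (expected counts from the
#' margins) is its score. Constant features score 0 with a warning.
#'
#' @param x Numeric matrix (samples x features).
#' @param y Binary (0/1) label vector; both classes must be present.
#' @param bins Number of equal-frequency bins (>= 2). Default 5.
#' @return Numeric vector of nonnegative scores, one per feature.
#' @export
chi_square_feature_scores <- function(x, y, bins = 5L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (bins < 2L) stop("bins must be >= 2")
  vapply(seq_len(ncol(x)), function(j) {
    b <- .discretize(x[, j], bins)
    if (is.null(b)) {
      warning("feature ", j, " is constant; chi-square score set to 0")
      return(0)
    }
    tab <- table(b, y)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    keep <- expected > 0
    chi_square_score(as.numeric(tab)[keep], as.numeric(expected)[keep])$statistic
  }, numeric(1))
}

#' Rank-and-keep pre-filter
#'
#' Scores every feature with the chosen filter (`"gini"` for forest-averaged
#' impurity importance, `"chi2"` for the chi-square dependency score) and
#' returns the indices of the `keep` top-ranked features, ties broken by the
#' lower index, sorted increasingly.
#'
#' @inheritParams chi_square_feature_scores
#' @param method `"gini"` or `"chi2"`.
#' @param keep Number of features to retain (1 <= keep <= ncol(x)).
#' @param ... Passed to the underlying scorer ([gini_feature_scores()] or
#'   [chi_square_feature_scores()]).
#' @return Integer vector of `keep` strictly increasing feature indices.
#' @export
prefilter <- function(x, y, method = c("gini", "chi2"), keep, ...) {
  method <- match.arg(method)
  x <- as.matrix(x)
  keep <- as.integer(keep)
  if (keep < 1L || keep > ncol(x)) stop("keep must be in [1, n_features]")
  scores <- switch(method,
    gini = gini_feature_scores(x, y, ...),
    chi2 = chi_square_feature_scores(x, y, ...)
  )
  ranked <- order(-scores, seq_along(scores))
  sort(ranked[seq_len(keep)])
}
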