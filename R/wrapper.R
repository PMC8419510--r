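# Wrapper feature selection: feature subsets are encoded as continuous
# positions in [0,1]^p, thresholded into binary masks, and scored by a
# blend of cross-validated classifier error and subset size; WHO searches
# that landscape. Fitness is deterministic per seed (fixed fold assignment),
# which also lets select_features() cache fitness per mask.

.validate_dataset <- function(x, y) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("feature matrix must be numeric")
  if (anyNA(x)) stop("feature matrix must not contain missing values")
  if (nrow(x) < 4L) stop("need at least 4 samples")
  if (ncol(x) < 2L) stop("need at least 2 features")
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("labels must match the number of rows")
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  list(x = x, y = y)
}

#' Fitness configuration of the wrapper objective
#'
#' The minimized wrapper objective is
#' `error_weight * cv_error + (1 - error_weight) * n_selected / n_features`,
#' where `cv_error` is the stratified cross-validated misclassification rate
#' of the configured classifier restricted to the selected features. The
#' default weight 0.99 makes accuracy dominate while still breaking ties
#' toward smaller subsets.
#'
#' @param error_weight Weight of the error term, in \[0, 1\]. Default 0.99.
#' @param classifier `"knn"` (default; deterministic, distance ties broken by
#'   index) or `"linear"` (logistic regression with a linear decision
#'   boundary, standing in for a linear SVM).
#' @param knn_k Odd neighbourhood size for kNN. Default 5.
#' @param cv_folds Number of stratified folds (>= 2). Default 5.
#' @param threshold Binarization cut in (0, 1). Default 0.5.
#' @param seed Integer seed controlling the fold assignment. Default 1.
#' @return An object of class `fitness_config`.
#' @export
fitness_config <- function(error_weight = 0.99,
                           classifier = c("knn", "linear"),
                           knn_k = 5L,
                           cv_folds = 5L,
                           threshold = 0.5,
                           seed = 1L) {
  classifier <- match.arg(classifier)
  if (error_weight < 0 || error_weight > 1) {
    stop("error_weight must be in [0, 1]")
  }
  knn_k <- as.integer(knn_k)
  if (knn_k < 1L || knn_k %% 2L == 0L) stop("knn_k must be a positive odd integer")
  cv_folds <- as.integer(cv_folds)
  if (cv_folds < 2L) stop("cv_folds must be >= 2")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  structure(
    list(error_weight = error_weight, classifier = classifier, knn_k = knn_k,
         cv_folds = cv_folds, threshold = threshold, seed = as.integer(seed)),
    class = "fitness_config"
  )
}

#' Threshold a continuous position into a selection mask
#'
#' `selected[j] = 1` iff `position[j] > threshold`. An all-zero mask is
#' repaired by forcing the single largest component to 1 (first index on
#' ties), so every mask selects at least one feature.
#'
#' @param position Numeric vector with components in \[0, 1\].
#' @param threshold Cut point in (0, 1). Default 0.5.
#' @return A list of class `selection_mask` with `selected` (0/1 integer
#'   vector) and `count`.
#' @examples
#' binarize(c(0.9, 0.1, 0.6))$selected  # 1 0 1
#' @export
binarize <- function(position, threshold = 0.5) {
  selected <- as.integer(position > threshold)
  if (sum(selected) == 0L) {
    selected[which.max(position)] <- 1L
  }
  structure(list(selected = selected, count = sum(selected)),
            class = "selection_mask")
}

# Stratified fold assignment, deterministic in the seed. Every fold's
# training set keeps both classes provided each class has >= 2 members.
.make_folds <- function(y, k, seed) {
  if (min(table(y)) < 2L) stop("each class needs at least 2 samples for CV")
  k <- min(k, min(table(y)))  # re-stratification: never more folds than the
                              # rarer class can populate
  folds <- integer(length(y))
  with_local_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Deterministic k-nearest-neighbour prediction; distance ties are resolved
# by the lower training index, vote ties by the single nearest neighbour.
.knn_predict <- function(train_x, train_y, test_x, k) {
  k <- min(k, nrow(train_x))
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * tcrossprod(test_x, train_x)
  apply(d2, 1L, function(row) {
    nn <- order(row, seq_along(row))[seq_len(k)]
    share <- mean(train_y[nn])
    if (share > 0.5) 1L else if (share < 0.5) 0L else train_y[nn[1L]]
  })
}

.linear_predict <- function(train_x, train_y, test_x) {
  df <- as.data.frame(train_x)
  names(df) <- paste0("v", seq_len(ncol(train_x)))
  df$.y <- train_y
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial())
  )
  nd <- as.data.frame(test_x)
  names(nd) <- paste0("v", seq_len(ncol(test_x)))
  p <- suppressWarnings(stats::predict(fit, newdata = nd, type = "response"))
  as.integer(p > 0.5)
}

#' Cross-validated predictions for a feature subset
#'
#' Runs the configured classifier on the selected columns under the
#' deterministic stratified fold split and returns out-of-fold predictions
#' for every sample.
#'
#' @param mask A [binarize()] mask (or 0/1 vector).
#' @param x Numeric feature matrix.
#' @param y Binary labels.
#' @param fc A [fitness_config()].
#' @return Integer vector of out-of-fold predicted labels.
#' @export
cv_predictions <- function(mask, x, y, fc) {
  ds <- .validate_dataset(x, y)
  sel <- if (inherits(mask, "selection_mask")) mask$selected else as.integer(mask)
  if (sum(sel) < 1L) stop("mask must select at least one feature")
  xs <- ds$x[, sel == 1L, drop = FALSE]
  folds <- .make_folds(ds$y, fc$cv_folds, fc$seed)
  pred <- integer(length(ds$y))
  for (f in sort(unique(folds))) {
    te <- folds == f
    pred[te] <- switch(fc$classifier,
      knn = .knn_predict(xs[!te, , drop = FALSE], ds$y[!te],
                         xs[te, , drop = FALSE], fc$knn_k),
      linear = .linear_predict(xs[!te, , drop = FALSE], ds$y[!te],
                               xs[te, , drop = FALSE])
    )
  }
  pred
}

#' Wrapper fitness of a feature subset
#'
#' `error_weight * cv_error + (1 - error_weight) * count / n_features`,
#' minimized. Deterministic given `fc$seed`.
#'
#' @inheritParams cv_predictions
#' @return A single finite fitness value.
#' @export
subset_fitness <- function(mask, x, y, fc = fitness_config()) {
  sel <- if (inherits(mask, "selection_mask")) mask$selected else as.integer(mask)
  pred <- cv_predictions(sel, x, y, fc)
  err <- mean(pred != as.integer(y))
  fc$error_weight * err + (1 - fc$error_weight) * sum(sel) / length(sel)
}

# Mask-level fitness cache shared by the searchers: the objective landscape
# only depends on the binary mask, so continuous probes hitting the same
# mask cost one lookup.
.masked_objective <- function(x, y, fc) {
  cache <- new.env(parent = emptyenv())
  n_distinct <- 0L
  fn <- function(position) {
    mask <- binarize(position, fc$threshold)
    key <- paste(mask$selected, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- subset_fitness(mask, x, y, fc)
    cache[[key]] <- val
    n_distinct <<- n_distinct + 1L
    val
  }
  list(fn = fn, cache = cache)
}

#' WHO wrapper feature selection
#'
#' Runs [who_optimize()] over `[0, 1]^p` with the masked wrapper fitness as
#' objective and returns the best mask found.
#'
#' @param x Numeric feature matrix (samples x features).
#' @param y Binary (0/1) labels, both classes present.
#' @param who_cfg A [who_config()]; defaults to the reference protocol of 30
#'   candidates and 15 iterations.
#' @param fc A [fitness_config()].
#' @return An object of class `who_selection`: `mask` (a `selection_mask`),
#'   `fitness`, `trace`, `evaluations`, `feature_names`, and the two config
#'   objects.
#' @examples
#' d <- generate_features(synthetic_spec(n_samples = 60, n_informative = 2,
#'                                       n_redundant = 0, n_noise = 4, seed = 2))
#' sel <- select_features(d$x, d$y, who_config(iterations = 5, seed = 2))
#' sel$mask$count
#' @export
select_features <- function(x, y, who_cfg = who_config(), fc = fitness_config()) {
  ds <- .validate_dataset(x, y)
  p <- ncol(ds$x)
  obj <- .masked_objective(ds$x, ds$y, fc)
  bounds <- who_bounds(0, 1, dimension = p)
  res <- who_optimize(obj$fn, bounds, who_cfg)
  mask <- binarize(res$best_position, fc$threshold)
  structure(
    list(
      mask = mask,
      fitness = res$best_fitness,
      trace = res$trace,
      evaluations = res$evaluations,
      feature_names = colnames(ds$x),
      who_config = res$config,
      fitness_config = fc
    ),
    class = "who_selection"
  )
}

#' @export
print.who_selection <- function(x, ...) {
  cat("WHO feature selection\n")
  cat("  selected:", x$mask$count, "of", length(x$mask$selected), "features\n")
  cat("  fitness: ", format(x$fitness, digits = 8), "\n")
  invisible(x)
}

# Evaluation budget WHO consumes per run, used to hand baselines a matched
# budget: per candidate-iteration there are milling_steps probe evaluations
# plus (at most) the local, instinct/starvation, and pressure re-evaluations.
.who_budget <- function(who_cfg) {
  who_cfg$population_size * who_cfg$iterations * (who_cfg$milling_steps + 3L)
}

#' Baseline subset searchers
#'
#' Budget-matched comparators for the WHO wrapper: `"random"` keeps the best
#' of `budget` uniformly drawn masks; `"hillclimb"` starts from a random mask
#' and repeatedly takes the best single-bit flip until no flip improves or
#' the budget is exhausted.
#'
#' @inheritParams select_features
#' @param method `"random"` or `"hillclimb"`.
#' @param budget Number of fitness evaluations allowed (cached masks count
#'   once per distinct mask visit).
#' @param seed Integer seed for the search's own draws.
#' @return A `who_selection` object (with `trace` the best-so-far fitness
#'   after each evaluation block).
#' @export
baseline_search <- function(x, y, method = c("random", "hillclimb"),
                            budget = NULL, fc = fitness_config(), seed = 1L,
                            who_cfg = who_config()) {
  method <- match.arg(method)
  ds <- .validate_dataset(x, y)
  p <- ncol(ds$x)
  if (is.null(budget)) budget <- .who_budget(who_cfg)
  budget <- as.integer(budget)
  if (budget < 1L) stop("budget must be >= 1")
  obj <- .masked_objective(ds$x, ds$y, fc)
  score_mask <- function(sel) obj$fn(ifelse(sel == 1L, 1, 0))

  best_sel <- NULL
  best_fit <- Inf
  trace <- numeric(0)
  with_local_seed(seed, {
    if (method == "random") {
      for (b in seq_len(budget)) {
        sel <- stats::rbinom(p, 1L, 0.5)
        if (sum(sel) == 0L) sel[sample.int(p, 1L)] <- 1L
        f <- score_mask(sel)
        if (f < best_fit) { best_fit <- f; best_sel <- sel }
        trace[b] <- best_fit
      }
    } else {
      sel <- stats::rbinom(p, 1L, 0.5)
      if (sum(sel) == 0L) sel[sample.int(p, 1L)] <- 1L
      best_fit <- score_mask(sel)
      best_sel <- sel
      used <- 1L
      trace <- best_fit
      repeat {
        cand_fit <- rep(Inf, p)
        for (j in seq_len(p)) {
          if (used >= budget) break
          flip <- best_sel
          flip[j] <- 1L - flip[j]
          if (sum(flip) == 0L) next
          cand_fit[j] <- score_mask(flip)
          used <- used + 1L
        }
        jbest <- which.min(cand_fit)
        if (!is.finite(cand_fit[jbest]) || cand_fit[jbest] >= best_fit) break
        best_sel[jbest] <- 1L - best_sel[jbest]
        best_fit <- cand_fit[jbest]
        trace[length(trace) + 1L] <- best_fit
        if (used >= budget) break
      }
    }
  })

  mask <- structure(list(selected = as.integer(best_sel),
                         count = sum(best_sel)), class = "selection_mask")
  structure(
    list(mask = mask, fitness = best_fit, trace = trace,
         evaluations = budget, feature_names = colnames(ds$x),
         who_config = NULL, fitness_config = fc, method = method),
    class = "who_selection"
  )
}

#' Repeated independent selection runs
#'
#' Executes [select_features()] `n_runs` times with seeds `seed, seed + 1,
#' ...` (the fitness seed, hence the CV folds, is held fixed so runs explore
#' the same landscape) and aggregates the per-run best fitness values with
#' [run_statistics()].
#'
#' @inheritParams select_features
#' @param n_runs Number of independent runs (>= 2). Default 35.
#' @return A list of class `who_repeated`: `stats` (a `run_stats`), `runs`
#'   (list of `who_selection`), `best_run` (index of the best run),
#'   `selected_counts`.
#' @export
repeated_runs <- function(x, y, who_cfg = who_config(), fc = fitness_config(),
                          n_runs = 35L) {
  n_runs <- as.integer(n_runs)
  if (n_runs < 2L) stop("n_runs must be >= 2")
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- who_cfg
    cfg$seed <- who_cfg$seed + r - 1L
    runs[[r]] <- select_features(x, y, cfg, fc)
  }
  fits <- vapply(runs, function(s) s$fitness, numeric(1))
  best_run <- which.min(fits)
  structure(
    list(
      stats = run_statistics(fits),
      runs = runs,
      best_run = best_run,
      selected_counts = vapply(runs, function(s) s$mask$count, integer(1))
    ),
    class = "who_repeated"
  )
}

#' Exhaustive subset search (oracle)
#'
#' Evaluates every nonempty mask over `p` features (feasible for `p <= 20`)
#' and returns the minimum-fitness mask. Used as the ground-truth comparator
#' for the stochastic searchers on small problems.
#'
#' @inheritParams select_features
#' @return A `who_selection` with the optimal mask and fitness.
#' @export
exhaustive_search <- function(x, y, fc = fitness_config()) {
  ds <- .validate_dataset(x, y)
  p <- ncol(ds$x)
  if (p > 20L) stop("exhaustive_search is limited to 20 features")
  best_fit <- Inf
  best_sel <- NULL
  for (code in seq_len(2L^p - 1L)) {
    sel <- as.integer(bitwAnd(bitwShiftR(code, seq_len(p) - 1L), 1L))
    f <- subset_fitness(sel, ds$x, ds$y, fc)
    if (f < best_fit) { best_fit <- f; best_sel <- sel }
  }
  mask <- structure(list(selected = best_sel, count = sum(best_sel)),
                    class = "selection_mask")
  structure(
    list(mask = mask, fitness = best_fit, trace = best_fit,
         evaluations = 2L^p - 1L, feature_names = colnames(ds$x),
         who_config = NULL, fitness_config = fc, method = "exhaustive"),
    class = "who_selection"
  )
}
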