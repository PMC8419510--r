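# Synthetic labeled feature matrices emulating the statistics of a
# high-redundancy deep-feature vector: a few class-informative Gaussian
# features, correlated redundant copies of them, and independent noise.
# Also provides the analytic benchmark objectives used to exercise the raw
# optimizer.

#' Specification of a synthetic feature matrix
#'
#' The generative model is Gaussian class-conditional: informative features
#' have unit variance and class means at +/- `effect_size / 2`; each
#' redundant feature is `rho * f + sqrt(1 - rho^2) * noise` for a randomly
#' chosen informative feature `f` (population correlation `rho` with its
#' source); noise features are standard normal, independent of the label.
#' Columns are shuffled, with the ground-truth role of every column tracked.
#'
#' @param n_samples Number of rows. Default 300.
#' @param n_informative,n_redundant,n_noise Counts of each feature role.
#'   Defaults 5 / 10 / 35 (a 50-feature matrix dominated by noise).
#' @param effect_size Class-mean separation in SD units. Default 1.5.
#' @param redundancy_rho Correlation of redundant copies with their source,
#'   in (0, 1). Default 0.8.
#' @param class_balance Probability of the positive class. Default 0.5.
#' @param rectify Logical; clamp negative values at zero, mimicking
#'   rectified deep activations. Default `FALSE`.
#' @param seed Integer seed. Default 1.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 300L,
                           n_informative = 5L, n_redundant = 10L,
                           n_noise = 35L,
                           effect_size = 1.5,
                           redundancy_rho = 0.8,
                           class_balance = 0.5,
                           rectify = FALSE,
                           seed = 1L) {
  n_samples <- as.integer(n_samples)
  n_informative <- as.integer(n_informative)
  n_redundant <- as.integer(n_redundant)
  n_noise <- as.integer(n_noise)
  if (n_informative < 1L) stop("n_informative must be >= 1")
  if (n_redundant < 0L || n_noise < 0L) stop("feature counts must be >= 0")
  if (n_samples < 4L) stop("n_samples must be >= 4")
  if (class_balance <= 0 || class_balance >= 1) {
    stop("class_balance must be in (0, 1)")
  }
  if (redundancy_rho <= 0 || redundancy_rho >= 1) {
    stop("redundancy_rho must be in (0, 1)")
  }
  structure(
    list(n_samples = n_samples, n_informative = n_informative,
         n_redundant = n_redundant, n_noise = n_noise,
         effect_size = effect_size, redundancy_rho = redundancy_rho,
         class_balance = class_balance, rectify = isTRUE(rectify),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic labeled feature matrix
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_data` with `x` (numeric matrix with
#'   column names `f001`, ...), `y` (0/1 labels, both classes guaranteed
#'   present), and ground-truth index sets `informative`, `redundant`,
#'   `noise` referring to columns of `x` after shuffling.
#' @examples
#' d <- generate_features(synthetic_spec(n_samples = 50, seed = 3))
#' dim(d$x); d$informative
#' @export
generate_features <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- spec$n_informative + spec$n_redundant + spec$n_noise
  with_local_seed(spec$seed, {
    n <- spec$n_samples
    y <- stats::rbinom(n, 1L, spec$class_balance)
    # both classes must be present for any supervised consumer
    if (all(y == 1L)) y[1L] <- 0L
    if (all(y == 0L)) y[1L] <- 1L

    mu <- ifelse(y == 1L, spec$effect_size / 2, -spec$effect_size / 2)
    informative <- matrix(stats::rnorm(n * spec$n_informative), n) + mu

    redundant <- NULL
    if (spec$n_redundant > 0L) {
      src <- sample.int(spec$n_informative, spec$n_redundant, replace = TRUE)
      rho <- spec$redundancy_rho
      redundant <- informative[, src, drop = FALSE] * rho +
        sqrt(1 - rho^2) * matrix(stats::rnorm(n * spec$n_redundant), n)
    }
    noise <- if (spec$n_noise > 0L) {
      matrix(stats::rnorm(n * spec$n_noise), n)
    } else NULL

    x <- cbind(informative, redundant, noise)
    roles <- rep(c("informative", "redundant", "noise"),
                 c(spec$n_informative, spec$n_redundant, spec$n_noise))
    perm <- sample.int(p)
    x <- x[, perm, drop = FALSE]
    roles <- roles[perm]
    if (spec$rectify) x[x < 0] <- 0
    colnames(x) <- sprintf("f%03d", seq_len(p))

    structure(
      list(
        x = x, y = y,
        informative = which(roles == "informative"),
        redundant = which(roles == "redundant"),
        noise = which(roles == "noise"),
        spec = spec
      ),
      class = "synthetic_data"
    )
  })
}

#' Analytic benchmark objectives
#'
#' Standard continuous test functions with known optima, used to exercise the
#' raw optimizer: `sphere` (`sum(x^2)`, optimum 0 at the origin, domain
#' \[-5, 5\]^d), `rastrigin` (`10 d + sum(x^2 - 10 cos(2 pi x))`, optimum 0
#' at the origin, domain \[-5.12, 5.12\]^d), and `quadratic1d`
#' (`(x - 2)^2`, optimum 0 at x = 2, domain \[0, 5\]).
#'
#' @param name One of `"sphere"`, `"rastrigin"`, `"quadratic1d"`.
#' @param dimension Positive integer (forced to 1 for `quadratic1d`).
#' @return A list of class `who_benchmark`: `fn` (the objective), `name`,
#'   `dimension`, `bounds` (a [who_bounds()]), `optimum_value`,
#'   `optimum_position`.
#' @examples
#' b <- benchmark_objective("sphere", 2)
#' b$fn(c(1, 1))  # 2
#' @export
benchmark_objective <- function(name = c("sphere", "rastrigin", "quadratic1d"),
                                dimension = 2L) {
  name <- match.arg(name)
  dimension <- as.integer(dimension)
  if (dimension < 1L) stop("dimension must be >= 1")
  obj <- switch(name,
    sphere = list(
      fn = function(x) sum(x^2),
      bounds = who_bounds(-5, 5, dimension = dimension),
      optimum_value = 0,
      optimum_position = rep(0, dimension)
    ),
    rastrigin = list(
      fn = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
      bounds = who_bounds(-5.12, 5.12, dimension = dimension),
      optimum_value = 0,
      optimum_position = rep(0, dimension)
    ),
    quadratic1d = {
      dimension <- 1L
      list(
        fn = function(x) (x[1L] - 2)^2,
        bounds = who_bounds(0, 5, dimension = 1L),
        optimum_value = 0,
        optimum_position = 2
      )
    }
  )
  structure(c(list(name = name, dimension = dimension), obj),
            class = "who_benchmark")
}
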