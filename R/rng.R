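# Seeded random sources. All stochastic code in the package draws through one
# of these objects (or through with_local_seed) so that runs never disturb the
# caller's .Random.seed and identical seeds give bit-identical results.

.get_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

.set_global_seed <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Evaluate code under a temporary seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state exactly. Used internally wherever a deterministic,
#' isolated draw sequence is needed (fold assignment, data generation,
#' baseline searches).
#'
#' @param seed Integer seed (kept below 2^31).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_local_seed <- function(seed, code) {
  old <- .get_global_seed()
  on.exit(.set_global_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  code
}

.unit_vector_draw <- function(d) {
  repeat {
    v <- stats::rnorm(d)
    nrm <- sqrt(sum(v * v))
    if (nrm > 1e-12) return(v / nrm)
  }
}

#' Seeded random source for the optimizer
#'
#' A `who_rng` supplies the two primitive draws the herd dynamics need:
#' `theta()`, uniform on \[0, 1\], and `unit(d)`, a random direction of
#' Euclidean norm 1 in `d` dimensions (an isotropic Gaussian, normalized).
#' The object carries its own RNG state, so interleaving draws with other
#' code cannot change a run's trajectory.
#'
#' @param seed Integer seed; the same seed reproduces the same draw sequence.
#' @return An object of class `who_rng` with elements `theta` (function of no
#'   arguments), `unit` (function of the dimension), and `seed`.
#' @examples
#' r <- who_rng(1)
#' r$theta()
#' sqrt(sum(r$unit(8)^2))  # always 1
#' @export
who_rng <- function(seed) {
  seed <- as.integer(seed)
  env <- new.env(parent = emptyenv())
  env$state <- NULL
  draw <- function(fn) {
    old <- .get_global_seed()
    on.exit(.set_global_seed(old), add = TRUE)
    if (is.null(env$state)) set.seed(seed) else .set_global_seed(env$state)
    res <- fn()
    env$state <- .get_global_seed()
    res
  }
  structure(
    list(
      theta = function() draw(function() stats::runif(1L)),
      unit = function(d) draw(function() .unit_vector_draw(d)),
      seed = seed
    ),
    class = "who_rng"
  )
}

#' Deterministic random source with scripted draws
#'
#' Returns a `who_rng` whose `theta()` and `unit()` calls pop values from
#' fixed queues. Intended for tests that inject specific draws into a single
#' herd operation; exhausting a queue is an error.
#'
#' @param thetas Numeric vector of values returned by successive `theta()` calls.
#' @param units List of numeric vectors returned by successive `unit(d)` calls
#'   (each must already have the requested length; the norm is not checked so
#'   tests can force axis-aligned directions).
#' @return A `who_rng` object.
#' @export
fixed_rng <- function(thetas = numeric(), units = list()) {
  env <- new.env(parent = emptyenv())
  env$thetas <- as.numeric(thetas)
  env$units <- units
  structure(
    list(
      theta = function() {
        if (length(env$thetas) == 0L) stop("fixed_rng: theta queue exhausted")
        v <- env$thetas[[1L]]
        env$thetas <- env$thetas[-1L]
        v
      },
      unit = function(d) {
        if (length(env$units) == 0L) stop("fixed_rng: unit queue exhausted")
        v <- as.numeric(env$units[[1L]])
        env$units <- env$units[-1L]
        if (length(v) != d) stop("fixed_rng: scripted unit vector has wrong length")
        v
      },
      seed = NA_integer_
    ),
    class = "who_rng"
  )
}
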