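# Wildebeest Herd Optimization (WHO): a population metaheuristic for
# box-bounded continuous minimization. Each iteration every candidate
# performs a local "milling" probe phase, blends toward its best probe,
# may follow a fitter random peer (herd instinct), takes a large random
# escape step if its fitness worsened (starvation avoidance), and is pulled
# onto the global best when at an intermediate distance from it (herd
# pressure); once per iteration the worst candidate is re-seeded next to the
# global best (social memory). The best-ever solution is retained (elitism).

#' Box bounds for the search domain
#'
#' @param lower,upper Numeric vectors of equal length giving the per-dimension
#'   lower and upper limits. Scalars are recycled to `dimension` if given.
#' @param dimension Optional integer; required when `lower`/`upper` are scalars.
#' @return An object of class `who_bounds` with fields `lower`, `upper`,
#'   `dimension`.
#' @examples
#' who_bounds(-5, 5, dimension = 10)
#' who_bounds(c(0, 0), c(1, 2))
#' @export
who_bounds <- function(lower, upper, dimension = NULL) {
  if (!is.null(dimension)) {
    dimension <- as.integer(dimension)
    if (dimension < 1L) stop("dimension must be a positive integer")
    if (length(lower) == 1L) lower <- rep(as.numeric(lower), dimension)
    if (length(upper) == 1L) upper <- rep(as.numeric(upper), dimension)
  }
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper)) {
    stop("lower and upper must have the same length")
  }
  if (length(lower) < 1L) stop("bounds must have at least one dimension")
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite")
  }
  if (any(lower > upper)) {
    stop("invalid bounds: lower exceeds upper in some dimension")
  }
  structure(
    list(lower = lower, upper = upper, dimension = length(lower)),
    class = "who_bounds"
  )
}

.clamp <- function(x, bounds) {
  pmin(pmax(x, bounds$lower), bounds$upper)
}

#' Configuration of the WHO optimizer
#'
#' Tunable parameters of the herd dynamics. Defaults follow a
#' small-local-step / strong-peer-pull regime: three milling probes per
#' candidate, a learning rate of 10% of the mean bound range, a mild blend
#' toward the best probe and a strong blend toward fitter peers. The two
#' scale-dependent parameters (`learning_rate`, `crowding_threshold`) default
#' to `NULL` and are resolved from the bounds at optimization time.
#'
#' @param population_size Number of candidates N (>= 2). Default 30.
#' @param iterations Number of herd iterations. Default 15.
#' @param milling_steps Number of local probes n per candidate per iteration.
#' @param learning_rate Step length epsilon of the milling and herd-pressure
#'   moves; `NULL` resolves to `0.1 * mean(upper - lower)`.
#' @param alpha1,beta1 Leader weights of the local move
#'   `x <- alpha1 * z_best + beta1 * (x - z_best)`.
#' @param alpha2,beta2 Leader weights of the peer-following move
#'   `x <- alpha2 * x + beta2 * x_peer`.
#' @param crowding_threshold Upper distance eta of the herd-pressure window;
#'   `NULL` resolves to `0.3 * sqrt(sum((upper - lower)^2))`.
#' @param pressure_lower_bound Lower distance of the herd-pressure window
#'   (default 1): the pull applies when
#'   `pressure_lower_bound < ||x_best - x|| < eta`, so the rule is inert
#'   whenever `eta <= pressure_lower_bound`.
#' @param social_memory_radius Radius of the once-per-iteration re-seed of the
#'   worst candidate around the global best. Default 0.1.
#' @param social_memory Logical; set `FALSE` to disable the re-seed phase.
#' @param seed Integer seed used when no explicit `who_rng` is supplied.
#' @return An object of class `who_config`.
#' @export
who_config <- function(population_size = 30L,
                       iterations = 15L,
                       milling_steps = 3L,
                       learning_rate = NULL,
                       alpha1 = 0.9, beta1 = 0.3,
                       alpha2 = 0.2, beta2 = 0.8,
                       crowding_threshold = NULL,
                       pressure_lower_bound = 1,
                       social_memory_radius = 0.1,
                       social_memory = TRUE,
                       seed = 1L) {
  population_size <- as.integer(population_size)
  iterations <- as.integer(iterations)
  milling_steps <- as.integer(milling_steps)
  if (population_size < 2L) stop("population_size must be >= 2")
  if (iterations < 1L) stop("iterations must be >= 1")
  if (milling_steps < 1L) stop("milling_steps must be >= 1")
  if (!is.null(learning_rate) && learning_rate < 0) {
    stop("learning_rate must be >= 0")
  }
  if (!is.null(crowding_threshold) && crowding_threshold <= 0) {
    stop("crowding_threshold must be > 0")
  }
  if (social_memory_radius < 0) stop("social_memory_radius must be >= 0")
  structure(
    list(
      population_size = population_size,
      iterations = iterations,
      milling_steps = milling_steps,
      learning_rate = learning_rate,
      alpha1 = alpha1, beta1 = beta1,
      alpha2 = alpha2, beta2 = beta2,
      crowding_threshold = crowding_threshold,
      pressure_lower_bound = pressure_lower_bound,
      social_memory_radius = social_memory_radius,
      social_memory = isTRUE(social_memory),
      seed = as.integer(seed)
    ),
    class = "who_config"
  )
}

# Fill the scale-dependent defaults from the bounds.
.resolve_config <- function(config, bounds) {
  rng_span <- bounds$upper - bounds$lower
  if (is.null(config$learning_rate)) {
    config$learning_rate <- 0.1 * mean(rng_span)
  }
  if (is.null(config$crowding_threshold)) {
    config$crowding_threshold <- 0.3 * sqrt(sum(rng_span^2))
    if (config$crowding_threshold == 0) config$crowding_threshold <- .Machine$double.eps
  }
  config
}

.new_candidate <- function(position, fitness = NA_real_) {
  structure(list(position = position, fitness = fitness), class = "who_candidate")
}

.eval_objective <- function(objective, position) {
  value <- objective(position)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop(
      "objective returned a non-finite value at position (",
      paste(signif(position, 6), collapse = ", "), ")"
    )
  }
  as.numeric(value)
}

#' Initialize a WHO population
#'
#' Draws `population_size` candidates uniformly within the bounds. Fitness is
#' left unevaluated (`NA`).
#'
#' @param bounds A [who_bounds()] object.
#' @param config A [who_config()] object.
#' @param rng A [who_rng()] source.
#' @return An object of class `who_population`: a list with `candidates`
#'   (list of candidates), `best` (`NULL` until evaluated), `iteration = 0`.
#' @export
initialize_population <- function(bounds, config, rng) {
  d <- bounds$dimension
  span <- bounds$upper - bounds$lower
  candidates <- vector("list", config$population_size)
  for (i in seq_len(config$population_size)) {
    u <- vapply(seq_len(d), function(j) rng$theta(), numeric(1))
    candidates[[i]] <- .new_candidate(bounds$lower + u * span)
  }
  structure(
    list(candidates = candidates, best = NULL, iteration = 0L),
    class = "who_population"
  )
}

#' Milling: the local probe phase
#'
#' Generates `milling_steps` probes `z = x + epsilon * theta * v` around the
#' candidate, with a fresh uniform `theta` and random unit direction `v` per
#' probe, clamps them to the bounds, and returns the probe with the smallest
#' objective value.
#'
#' @param candidate A candidate (list with `position`).
#' @param objective Function mapping a position to a finite scalar.
#' @param bounds A [who_bounds()] object.
#' @param config A resolved [who_config()] (finite `learning_rate`).
#' @param rng A [who_rng()] source.
#' @return A list of class `who_milling` with `probes` (matrix, one row per
#'   probe), `values`, `best_probe`, `best_value`.
#' @export
milling <- function(candidate, objective, bounds, config, rng) {
  config <- .resolve_config(config, bounds)
  d <- bounds$dimension
  n <- config$milling_steps
  probes <- matrix(NA_real_, nrow = n, ncol = d)
  values <- numeric(n)
  for (s in seq_len(n)) {
    theta <- rng$theta()
    v <- rng$unit(d)
    z <- .clamp(candidate$position + config$learning_rate * theta * v, bounds)
    probes[s, ] <- z
    values[s] <- .eval_objective(objective, z)
  }
  k <- which.min(values)
  structure(
    list(probes = probes, values = values,
         best_probe = probes[k, ], best_value = values[k]),
    class = "who_milling"
  )
}

#' Blend toward the best milling probe
#'
#' Moves the candidate to `alpha1 * z_best + beta1 * (x - z_best)`, clamped to
#' the bounds, and re-evaluates its fitness.
#'
#' @inheritParams milling
#' @param milling_set The result of [milling()].
#' @return The updated candidate.
#' @export
local_update <- function(candidate, milling_set, objective, bounds, config) {
  if (is.null(milling_set$best_probe)) stop("milling_set has no probes")
  z <- milling_set$best_probe
  pos <- .clamp(config$alpha1 * z + config$beta1 * (candidate$position - z), bounds)
  .new_candidate(pos, .eval_objective(objective, pos))
}

#' Herd instinct: follow a fitter random peer
#'
#' When the peer's fitness is strictly better, the candidate moves to
#' `alpha2 * x + beta2 * x_peer` (clamped, fitness re-evaluated); otherwise
#' it is returned unchanged. The peer's position represents a richer food
#' source the herd drifts toward.
#'
#' @inheritParams milling
#' @param peer Another candidate with evaluated fitness.
#' @return The (possibly updated) candidate.
#' @export
herd_instinct <- function(candidate, peer, objective, bounds, config) {
  if (is.na(peer$fitness) || is.na(candidate$fitness)) {
    stop("herd_instinct requires evaluated fitness on both candidates")
  }
  if (!(peer$fitness < candidate$fitness)) {
    return(candidate)
  }
  pos <- .clamp(config$alpha2 * candidate$position + config$beta2 * peer$position,
                bounds)
  .new_candidate(pos, .eval_objective(objective, pos))
}

#' Starvation avoidance: escape a worsening region
#'
#' Adds `theta * (upper - lower) (*) v` componentwise (a random fraction of
#' the full bound range along a random direction), clamps, and re-evaluates.
#' In the full optimizer this move is applied only to candidates whose
#' fitness worsened within the current iteration.
#'
#' @inheritParams milling
#' @return The updated candidate.
#' @export
starvation_avoidance <- function(candidate, objective, bounds, rng) {
  theta <- rng$theta()
  v <- rng$unit(bounds$dimension)
  pos <- .clamp(candidate$position + theta * (bounds$upper - bounds$lower) * v,
                bounds)
  .new_candidate(pos, .eval_objective(objective, pos))
}

#' Herd pressure: collapse onto the global best
#'
#' If the Euclidean distance between the candidate and the global best lies
#' strictly between `pressure_lower_bound` and `crowding_threshold` (eta),
#' the candidate is replaced by `x_best + epsilon * u` for a random unit
#' direction `u` (clamped, re-evaluated); otherwise it is unchanged. With the
#' default lower bound of 1 the rule is inert whenever `eta <= 1`.
#'
#' @inheritParams milling
#' @param best The current global-best candidate.
#' @return The (possibly updated) candidate.
#' @export
herd_pressure <- function(candidate, best, objective, bounds, config, rng) {
  config <- .resolve_config(config, bounds)
  dist <- sqrt(sum((best$position - candidate$position)^2))
  if (!(dist > config$pressure_lower_bound && dist < config$crowding_threshold)) {
    return(candidate)
  }
  u <- rng$unit(bounds$dimension)
  pos <- .clamp(best$position + config$learning_rate * u, bounds)
  .new_candidate(pos, .eval_objective(objective, pos))
}

#' Social memory: re-seed the worst candidate near the best
#'
#' Replaces the position of the worst candidate (ties broken by lowest index)
#' with `x_best + r * u`, `r = social_memory_radius` (default 0.1), for a
#' random unit direction `u`; clamps, re-evaluates, and updates the global
#' best. The global best never worsens.
#'
#' @inheritParams milling
#' @param population A `who_population` whose candidates are all evaluated and
#'   whose `best` is set.
#' @return The updated population.
#' @export
social_memory <- function(population, objective, bounds, config, rng) {
  fits <- vapply(population$candidates, function(c) c$fitness, numeric(1))
  if (anyNA(fits) || is.null(population$best)) {
    stop("social_memory requires an evaluated population with a global best")
  }
  worst <- which.max(fits)  # which.max returns the first (lowest-index) tie
  u <- rng$unit(bounds$dimension)
  pos <- .clamp(population$best$position + config$social_memory_radius * u, bounds)
  cand <- .new_candidate(pos, .eval_objective(objective, pos))
  population$candidates[[worst]] <- cand
  if (cand$fitness < population$best$fitness) {
    population$best <- cand
  }
  population
}

#' Run the WHO optimizer
#'
#' Minimizes `objective` over the box `bounds`. Per iteration, each candidate
#' undergoes milling, the local blend, herd instinct toward a random distinct
#' peer, starvation avoidance (only if its fitness worsened within the
#' iteration), and herd pressure toward the global best; then social memory
#' re-seeds the worst candidate once. The best-ever candidate is tracked
#' elitistically, so the returned trace is nonincreasing.
#'
#' @param objective Function: numeric position vector -> finite scalar
#'   (minimized).
#' @param bounds A [who_bounds()] object.
#' @param config A [who_config()] object.
#' @param rng Optional [who_rng()]; defaults to `who_rng(config$seed)`.
#' @return An object of class `who_result`: `best_position`, `best_fitness`,
#'   `trace` (best-ever fitness after each iteration), `evaluations`
#'   (objective call count), and the resolved `config`.
#' @examples
#' sph <- function(x) sum(x^2)
#' res <- who_optimize(sph, who_bounds(-5, 5, dimension = 3),
#'                     who_config(iterations = 25, seed = 7))
#' res$best_fitness
#' @export
who_optimize <- function(objective, bounds, config = who_config(), rng = NULL) {
  stopifnot(inherits(bounds, "who_bounds"), inherits(config, "who_config"))
  if (is.null(rng)) rng <- who_rng(config$seed)
  config <- .resolve_config(config, bounds)
  n_eval <- 0L
  counted <- function(x) {
    n_eval <<- n_eval + 1L
    .eval_objective(objective, x)
  }

  pop <- initialize_population(bounds, config, rng)
  for (i in seq_along(pop$candidates)) {
    pop$candidates[[i]]$fitness <- counted(pop$candidates[[i]]$position)
  }
  fits <- vapply(pop$candidates, function(c) c$fitness, numeric(1))
  pop$best <- pop$candidates[[which.min(fits)]]

  n <- config$population_size
  trace <- numeric(config$iterations)
  for (it in seq_len(config$iterations)) {
    for (i in seq_len(n)) {
      cand <- pop$candidates[[i]]
      fit_before <- cand$fitness

      ms <- milling(cand, counted, bounds, config, rng)
      cand <- local_update(cand, ms, counted, bounds, config)

      # peer index drawn uniformly among the other candidates
      j <- 1L + floor(rng$theta() * (n - 1L))
      j <- min(j, n - 1L)
      others <- seq_len(n)[-i]
      cand <- herd_instinct(cand, pop$candidates[[others[j]]], counted, bounds,
                            config)

      if (cand$fitness > fit_before) {
        cand <- starvation_avoidance(cand, counted, bounds, rng)
      }

      cand <- herd_pressure(cand, pop$best, counted, bounds, config, rng)

      pop$candidates[[i]] <- cand
      if (cand$fitness < pop$best$fitness) pop$best <- cand
    }
    if (config$social_memory) {
      pop <- social_memory(pop, counted, bounds, config, rng)
    }
    trace[it] <- pop$best$fitness
  }
  pop$iteration <- config$iterations

  structure(
    list(
      best_position = pop$best$position,
      best_fitness = pop$best$fitness,
      trace = trace,
      evaluations = n_eval,
      config = config
    ),
    class = "who_result"
  )
}

#' @export
print.who_result <- function(x, ...) {
  cat("WHO optimization result\n")
  cat("  best fitness:", format(x$best_fitness, digits = 8), "\n")
  cat("  dimensions:  ", length(x$best_position), "\n")
  cat("  iterations:  ", length(x$trace), "\n")
  cat("  evaluations: ", x$evaluations, "\n")
  invisible(x)
}
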