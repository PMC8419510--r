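# Unit tests of the herd operations, each against its collapse /
# hand-arithmetic case, plus the optimizer-level contracts (elitism,
# determinism, containment).

test_that("who_bounds validates and recycles", {
  b <- who_bounds(-5, 5, dimension = 3)
  expect_equal(b$lower, rep(-5, 3))
  expect_equal(b$dimension, 3L)
  expect_error(who_bounds(c(0, 2), c(1, 1)), "lower exceeds upper")
  expect_error(who_bounds(0, Inf, dimension = 1), "finite")
})

test_that("who_rng is reproducible, isolated, and draws unit vectors", {
  r1 <- who_rng(42)
  r2 <- who_rng(42)
  expect_identical(r1$theta(), r2$theta())
  expect_identical(r1$unit(6), r2$unit(6))
  for (i in 1:20) {
    expect_equal(sqrt(sum(r1$unit(sample(1:12, 1))^2)), 1, tolerance = 1e-12)
  }
  # drawing through the rng must not disturb the global stream
  set.seed(7); a <- runif(3)
  set.seed(7); invisible(who_rng(1)$theta()); b <- runif(3)
  expect_identical(a, b)
})

test_that("initialize_population respects bounds and determinism", {
  cfg <- who_config(population_size = 30)
  b <- who_bounds(0, 1, dimension = 5)
  pop <- initialize_population(b, cfg, who_rng(1))
  expect_length(pop$candidates, 30L)
  pos <- do.call(rbind, lapply(pop$candidates, `[[`, "position"))
  expect_true(all(pos >= 0 & pos <= 1))
  expect_true(all(is.na(vapply(pop$candidates, `[[`, numeric(1), "fitness"))))

  deg <- initialize_population(who_bounds(0.5, 0.5, dimension = 1), cfg, who_rng(1))
  expect_true(all(vapply(deg$candidates, `[[`, numeric(1), "position") == 0.5))

  pop2 <- initialize_population(b, cfg, who_rng(1))
  expect_identical(pop, pop2)
})

test_that("milling follows z = x + eps * theta * v and clamps", {
  b <- who_bounds(-10, 10, dimension = 2)
  cand <- list(position = c(0, 0))
  sph <- function(x) sum(x^2)

  # scripted draw: theta = 1, v = (1, 0), eps = 0.5 -> probe (0.5, 0)
  cfg <- who_config(milling_steps = 1, learning_rate = 0.5)
  ms <- milling(cand, sph, b, cfg, fixed_rng(thetas = 1, units = list(c(1, 0))))
  expect_equal(ms$best_probe, c(0.5, 0))

  # eps = 0 collapses every probe onto x
  cfg0 <- who_config(milling_steps = 4, learning_rate = 0)
  ms0 <- milling(cand, sph, b, cfg0, who_rng(3))
  expect_true(all(ms0$probes == 0))

  # probe displacement never exceeds eps (unit direction, theta <= 1)
  cfg2 <- who_config(milling_steps = 50, learning_rate = 0.7)
  ms2 <- milling(list(position = c(1, 1)), sph, b, cfg2, who_rng(4))
  d <- sqrt(rowSums(sweep(ms2$probes, 2, c(1, 1))^2))
  expect_true(all(d <= 0.7 + 1e-12))
  expect_equal(ms2$best_value, min(ms2$values))

  expect_error(
    milling(cand, function(x) NaN, b, cfg, who_rng(1)),
    "non-finite"
  )
})

test_that("local_update blends toward the best probe", {
  b <- who_bounds(-10, 10, dimension = 2)
  sph <- function(x) sum(x^2)
  ms <- list(best_probe = c(0, 0))
  cand <- list(position = c(1, 1), fitness = 2)
  # alpha1 = 0.9, beta1 = 0.3, x = (1,1), z = (0,0) -> (0.3, 0.3)
  upd <- local_update(cand, ms, sph, b, who_config(alpha1 = 0.9, beta1 = 0.3))
  expect_equal(upd$position, c(0.3, 0.3))
  expect_equal(upd$fitness, 0.18)
  # collapse cases
  expect_equal(
    local_update(cand, list(best_probe = c(2, 3)), sph, b,
                 who_config(alpha1 = 1, beta1 = 0))$position,
    c(2, 3)
  )
  expect_equal(
    local_update(cand, list(best_probe = c(2, 3)), sph, b,
                 who_config(alpha1 = 0, beta1 = 1))$position,
    c(-1, -2)
  )
})

test_that("herd_instinct only follows strictly fitter peers", {
  b <- who_bounds(-10, 10, dimension = 2)
  sph <- function(x) sum(x^2)
  cand <- list(position = c(1, 1), fitness = 2)
  worse <- list(position = c(3, 3), fitness = 18)
  expect_identical(herd_instinct(cand, worse, sph, b, who_config()), cand)

  better <- list(position = c(0, 0), fitness = 0)
  moved <- herd_instinct(cand, better, sph, b,
                         who_config(alpha2 = 0.2, beta2 = 0.8))
  expect_equal(moved$position, c(0.2, 0.2))

  # alpha2 = 1, beta2 = 0: position fixed, fitness re-evaluated
  same <- herd_instinct(cand, better, sph, b, who_config(alpha2 = 1, beta2 = 0))
  expect_equal(same$position, c(1, 1))
  expect_equal(same$fitness, 2)
})

test_that("starvation_avoidance applies the scripted range step", {
  b <- who_bounds(0, 1, dimension = 1)
  obj <- function(x) x[1]
  cand <- list(position = 0.5, fitness = 0.5)
  # theta = 0.25, v = (1): 0.5 + 0.25 * (1 - 0) * 1 = 0.75
  out <- starvation_avoidance(cand, obj, b, fixed_rng(thetas = 0.25, units = list(1)))
  expect_equal(out$position, 0.75)
  # theta = 0 leaves the position unchanged
  out0 <- starvation_avoidance(cand, obj, b, fixed_rng(thetas = 0, units = list(1)))
  expect_equal(out0$position, 0.5)
})

test_that("herd_pressure applies only inside the distance window", {
  b <- who_bounds(-10, 10, dimension = 2)
  sph <- function(x) sum(x^2)
  best <- list(position = c(0, 0), fitness = 0)
  cfg <- who_config(crowding_threshold = 3, learning_rate = 0.5)

  far <- list(position = c(5, 5), fitness = 50)  # distance > eta: unchanged
  expect_identical(herd_pressure(far, best, sph, b, cfg, who_rng(1)), far)
  near <- list(position = c(0.5, 0), fitness = 0.25)  # distance < 1: unchanged
  expect_identical(herd_pressure(near, best, sph, b, cfg, who_rng(1)), near)

  mid <- list(position = c(2, 0), fitness = 4)  # 1 < 2 < 3: pulled onto best
  out <- herd_pressure(mid, best, sph, b, cfg,
                       fixed_rng(units = list(c(0, 1))))
  expect_equal(out$position, c(0, 0.5))
  expect_equal(sqrt(sum((out$position - best$position)^2)), cfg$learning_rate)
  # eps = 0 collapses exactly onto the best
  cfg0 <- who_config(crowding_threshold = 3, learning_rate = 0)
  out0 <- herd_pressure(mid, best, sph, b, cfg0, fixed_rng(units = list(c(0, 1))))
  expect_equal(out0$position, c(0, 0))
})

test_that("social_memory re-seeds the worst candidate near the best", {
  b <- who_bounds(-10, 10, dimension = 2)
  sph <- function(x) sum(x^2)
  cands <- list(
    list(position = c(0, 0), fitness = 0),
    list(position = c(5, 5), fitness = 50),
    list(position = c(1, 1), fitness = 2)
  )
  pop <- structure(list(candidates = cands, best = cands[[1]], iteration = 0L),
                   class = "who_population")
  out <- social_memory(pop, sph, b, who_config(), who_rng(1))
  moved <- out$candidates[[2]]$position
  expect_equal(sqrt(sum((moved - c(0, 0))^2)), 0.1, tolerance = 1e-12)
  expect_lte(out$best$fitness, 0)  # elitism: never degraded
})

test_that("collapse configuration leaves the population stationary", {
  # eps = 0, alpha1 = 1, beta1 = 0, alpha2 = 1, beta2 = 0, no social memory;
  # bounds chosen so the herd-pressure window (eta < 1) is inert.
  b <- who_bounds(0, 1, dimension = 5)
  cfg <- who_config(population_size = 10, iterations = 10, learning_rate = 0,
                    alpha1 = 1, beta1 = 0, alpha2 = 1, beta2 = 0,
                    social_memory = FALSE, seed = 5)
  sph <- function(x) sum(x^2)
  init <- initialize_population(b, cfg, who_rng(5))
  init_fits <- vapply(init$candidates, function(c) sph(c$position), numeric(1))
  res <- who_optimize(sph, b, cfg)
  expect_equal(res$best_fitness, min(init_fits))
  expect_true(all(res$trace == min(init_fits)))
})

test_that("optimize: constant objective, elitism, determinism, containment", {
  b <- who_bounds(-2, 2, dimension = 3)
  cfg <- who_config(population_size = 8, iterations = 12, seed = 9)
  res_const <- who_optimize(constant_objective(7), b, cfg)
  expect_equal(res_const$best_fitness, 7)

  # trace nonincreasing on an arbitrary rugged objective, several seeds
  rug <- function(x) sum(sin(3 * x) + 0.2 * x^2)
  for (s in 1:5) {
    cfg_s <- who_config(population_size = 8, iterations = 15, seed = s)
    r <- who_optimize(rug, b, cfg_s)
    expect_true(all(diff(r$trace) <= 0))
    expect_equal(r$best_fitness, r$trace[length(r$trace)])
  }

  # containment: record every evaluated position
  seen <- new.env(); seen$bad <- 0L
  watched <- function(x) {
    if (any(x < -2 - 1e-12) || any(x > 2 + 1e-12)) seen$bad <- seen$bad + 1L
    sum(x^2)
  }
  invisible(who_optimize(watched, b, who_config(population_size = 10,
                                                iterations = 20, seed = 3)))
  expect_identical(seen$bad, 0L)

  # bit-identical determinism
  r1 <- who_optimize(rug, b, cfg)
  r2 <- who_optimize(rug, b, cfg)
  expect_identical(r1, r2)

  expect_error(who_optimize(function(x) Inf, b, cfg), "non-finite")
})

test_that("WHO beats random search at equal budget where dimension bites", {
  # In 1-D, uniform random search at a matched budget reaches the same
  # ~1e-8 fitness floor as WHO on the quadratic, so the paired comparison
  # there is a coin flip; the sanity check is run on the 10-D sphere, where
  # random search degrades with dimension and a structured optimizer must
  # dominate.
  bm <- benchmark_objective("sphere", 10)
  wins <- 0L
  for (s in 1:10) {
    cfg <- who_config(population_size = 10, iterations = 20, seed = s)
    res <- who_optimize(bm$fn, bm$bounds, cfg)
    rnd_best <- with_local_seed(1000 + s, {
      xs <- matrix(runif(res$evaluations * 10, -5, 5), ncol = 10)
      min(rowSums(xs^2))
    })
    if (res$best_fitness <= rnd_best) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})
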