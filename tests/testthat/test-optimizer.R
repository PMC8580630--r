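test_that("chaotic map matches direct arithmetic and clips into (0,1)", {
  expect_equal(chaos_next(0.5, 2.3), 2.3 * 0.25 * sin(pi / 2))
  expect_equal(chaos_next(0.7, 2.3), 2.3 * 0.49 * sin(0.7 * pi),
               tolerance = 1e-12)
  # alpha near 4 escapes the unit interval and is reflected just inside it
  expect_lt(chaos_next(0.61, 4), 1)
  expect_gt(chaos_next(1e-9, 2.3), 0)
  expect_error(chaos_next(0, 2.3), "open interval")
  expect_error(chaos_next(1.2, 2.3), "open interval")
})

test_that("chaotic stream stays in (0,1) over 1e5 iterates", {
  f <- 0.37
  lo <- 1; hi <- 0
  for (i in 1:1e5) {
    f <- chaos_next(f, 2.3)
    if (f < lo) lo <- f
    if (f > hi) hi <- f
  }
  expect_gt(lo, 0)
  expect_lt(hi, 1)
})

test_that("population initialization respects bounds, degeneracy, determinism", {
  cfg0 <- teo_config(c(0, 0), c(0, 0), population_size = 6,
                     max_iterations = 5, chaos_f0 = 0.7)
  st <- initialize_population(cfg0)
  expect_true(all(st$temperatures == 0))
  expect_true(all(is.na(st$costs)))

  cfg <- teo_config(-1, 1, population_size = 1000, max_iterations = 5,
                    chaos_f0 = 0.7)
  st <- initialize_population(cfg)
  expect_gte(min(st$temperatures), -1)
  expect_lte(max(st$temperatures), 1)

  cfgs <- teo_config(c(-2, -2), c(3, 3), population_size = 10,
                     max_iterations = 5, variant = "teo")
  set.seed(123); a <- initialize_population(cfgs)
  set.seed(123); b <- initialize_population(cfgs)
  expect_identical(a$temperatures, b$temperatures)
})

test_that("configuration validation rejects bad inputs", {
  expect_error(teo_config(0, 1, population_size = 7), "even")
  expect_error(teo_config(1, 0), "bounds_low")
  expect_error(teo_config(0, 1, pr = 1.5), "pr")
  expect_error(teo_config(0, 1, m1 = 0.5), "control variables")
  expect_error(teo_config(0, 1, chaos_alpha = 5), "chaos_alpha")
})

test_that("cost ratio follows the shifted-cost convention", {
  expect_equal(cost_ratio(8, 8), 1)
  expect_equal(cost_ratio(0, 8), 0)
  expect_equal(cost_ratio(2, 8), 0.25)
  expect_equal(cost_ratio(0, 0), 1)  # all-equal population convention
})

test_that("a duplicated population at a convex optimum is a fixed point", {
  cfg <- teo_config(c(-5, -5), c(5, 5), population_size = 4,
                    max_iterations = 10, variant = "teo", pr = 0,
                    m1 = 0, m2 = 0, chaos_f0 = 0.7)
  set.seed(5)
  st <- initialize_population(cfg)
  st$temperatures <- matrix(1, 4, 2)  # all candidates identical, off-origin
  obj <- function(x) sum((x - 1)^2)
  st1 <- teo_step(st, obj, cfg)
  expect_equal(min(st1$costs), 0)
  expect_true(all(st1$temperatures == 1))
})

test_that("one cooling step contracts towards the environment in expectation", {
  cfg <- teo_config(-5, 5, population_size = 2, max_iterations = 1,
                    variant = "teo", pr = 0)
  obj <- function(x) x^2
  set.seed(99)
  moved <- replicate(5000, {
    st <- initialize_population(cfg)
    st$temperatures <- matrix(c(0, 1), 2, 1)
    st1 <- teo_step(st, obj, cfg)
    max(abs(st1$temperatures))   # position of the (former) cooling object
  })
  expect_lt(mean(moved), 1)
})

test_that("gaussian mutation has the multiplicative form and right moments", {
  x <- c(1.5, -2, 0.3)
  expect_identical(gaussian_mutate(x, 0), x)
  expect_identical(gaussian_mutate(rep(0, 5), 0.7), rep(0, 5))
  expect_error(gaussian_mutate(x, 1.5), "decay")
  set.seed(11)
  s <- replicate(1e5, gaussian_mutate(1, 1))
  expect_lt(abs(mean(s) - 1), 3 / sqrt(1e5))
  expect_lt(abs(sd(s) - 1), 3 / sqrt(2 * 1e5))
})

test_that("best-ever cost is monotone and all vectors stay in bounds", {
  cfg <- teo_config(c(-4, -4, -4), c(4, 4, 4), population_size = 10,
                    max_iterations = 40, memory_size = 1, seed = 21)
  obj <- function(x) sum(x^2) + cos(3 * x[1])
  set.seed(21)
  st <- initialize_population(cfg)
  best <- Inf
  for (i in 1:40) {
    st <- teo_step(st, obj, cfg)
    expect_gte(min(st$temperatures), -4)
    expect_lte(max(st$temperatures), 4)
    expect_lte(min(st$costs), best + 1e-12)
    best <- min(best, min(st$costs))
  }
  res <- teo_minimize(obj, cfg)
  expect_true(all(diff(res$history) <= 0))
  expect_true(all(res$best_vector >= -4 & res$best_vector <= 4))
  expect_equal(res$best_cost, min(res$history))
})

test_that("a constant objective is returned exactly", {
  cfg <- teo_config(c(0, 0), c(1, 1), population_size = 6,
                    max_iterations = 5, seed = 3)
  res <- teo_minimize(function(x) 4.2, cfg)
  expect_equal(res$best_cost, 4.2)
})

test_that("dTEO solves the 2-D sphere to high precision across seeds", {
  hits <- sapply(1:20, function(k) {
    cfg <- teo_config(c(-5, -5), c(5, 5), population_size = 120,
                      max_iterations = 100, seed = 2000 + k)
    teo_minimize(function(x) sum(x^2), cfg)$best_cost
  })
  expect_gte(mean(hits < 1e-6), 0.95)
})

test_that("non-finite objective values are logged and treated as worst", {
  cfg <- teo_config(-1, 1, population_size = 20, max_iterations = 3,
                    variant = "teo", seed = 9)
  obj <- function(x) if (x[1] > 0) NaN else x[1]^2
  w <- testthat::capture_warnings(res <- teo_minimize(obj, cfg))
  expect_true(any(grepl("non-finite", w)))
  expect_true(is.finite(res$best_cost))
})
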