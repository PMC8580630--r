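#' Configuration for the Thermal Exchange Optimization algorithms
#'
#' Builds and validates the parameter set shared by [teo_minimize()] and the
#' lower-level stepping functions. The optimizer treats each candidate
#' solution as the temperature vector of a cooling object relaxing towards a
#' paired "environment" object under Newton's law of cooling; the `dteo`
#' variant additionally drives its random draws from a sinusoidal chaotic map
#' and applies a multiplicative Gaussian mutation to the cooling half.
#'
#' @param bounds_low,bounds_high Numeric vectors of per-dimension box bounds
#'   (recycled against each other). Equal entries give a degenerate,
#'   single-point dimension.
#' @param population_size Even positive integer; candidates are split into a
#'   better (environment) half and a worse (cooling) half each iteration.
#' @param max_iterations Number of update sweeps.
#' @param variant `"dteo"` (chaotic stream + Gaussian mutation) or `"teo"`
#'   (uniform stream, no mutation).
#' @param pr Probability in `[0, 1]` that one randomly chosen dimension of a
#'   cooling object is reset towards a fresh in-bounds draw.
#' @param m1,m2 Control variables in `{0, 1}` scaling the environment
#'   temperature perturbation `(1 - (m1 + m2 (1 - t)) r)`.
#' @param memory_size Size of the elitist thermal-memory archive; defaults to
#'   `max(2, population_size %/% 10)`.
#' @param chaos_alpha Chaotic map gain in `(0, 4]`; the default 2.3 keeps the
#'   sinusoidal map in its chaotic regime without escaping `(0, 1)`.
#' @param chaos_f0 Seed of the chaotic stream in `(0, 1)`; when `NULL` it is
#'   drawn from the run RNG inside the basin of the map's chaotic attractor
#'   (0.5-0.9 for the default gain; orbits started outside that band decay
#'   towards zero and would freeze the stream).
#' @param reset_style `"printed"` multiplies the dimension-reset span by
#'   `exp(-gamma t)` (the formula as printed); `"plain"` omits that factor
#'   (classical TEO form).
#' @param mutate_all Mutate the whole population rather than only the cooling
#'   half (dteo only).
#' @param swap_roles Reserved flag for a second half-sweep with roles
#'   exchanged; off by default (no reverse pass is performed).
#' @param seed Optional integer seed for the run RNG.
#' @return An object of class `"teo_config"`.
#' @examples
#' cfg <- teo_config(c(-5, -5), c(5, 5), population_size = 20,
#'                   max_iterations = 25, seed = 1)
#' res <- teo_minimize(function(x) sum(x^2), cfg)
#' res$best_cost
#' @export
teo_config <- function(bounds_low, bounds_high,
                       population_size = 120L, max_iterations = 100L,
                       variant = c("dteo", "teo"),
                       pr = 0.3, m1 = 0, m2 = 1,
                       memory_size = NULL,
                       chaos_alpha = 2.3, chaos_f0 = NULL,
                       reset_style = c("printed", "plain"),
                       mutate_all = FALSE, swap_roles = FALSE,
                       seed = NULL) {
  variant <- match.arg(variant)
  reset_style <- match.arg(reset_style)
  n <- max(length(bounds_low), length(bounds_high))
  bounds_low <- rep_len(as.numeric(bounds_low), n)
  bounds_high <- rep_len(as.numeric(bounds_high), n)
  if (any(!is.finite(bounds_low)) || any(!is.finite(bounds_high)))
    stop("bounds must be finite", call. = FALSE)
  if (any(bounds_low > bounds_high))
    stop("bounds_low must not exceed bounds_high", call. = FALSE)
  population_size <- as.integer(population_size)
  if (population_size < 2L || population_size %% 2L != 0L)
    stop("population_size must be an even integer >= 2", call. = FALSE)
  max_iterations <- as.integer(max_iterations)
  if (max_iterations < 1L) stop("max_iterations must be >= 1", call. = FALSE)
  if (pr < 0 || pr > 1) stop("pr must lie in [0, 1]", call. = FALSE)
  if (!m1 %in% c(0, 1) || !m2 %in% c(0, 1))
    stop("m1 and m2 are control variables in {0, 1}", call. = FALSE)
  if (is.null(memory_size)) memory_size <- max(2L, population_size %/% 10L)
  memory_size <- as.integer(memory_size)
  if (memory_size < 0L) stop("memory_size must be non-negative", call. = FALSE)
  if (chaos_alpha <= 0 || chaos_alpha > 4)
    stop("chaos_alpha must lie in (0, 4]", call. = FALSE)
  if (!is.null(chaos_f0) && (chaos_f0 <= 0 || chaos_f0 >= 1))
    stop("chaos_f0 must lie in (0, 1)", call. = FALSE)
  structure(list(
    bounds_low = bounds_low, bounds_high = bounds_high, dim = n,
    population_size = population_size, max_iterations = max_iterations,
    variant = variant, pr = pr, m1 = m1, m2 = m2,
    memory_size = memory_size, chaos_alpha = chaos_alpha,
    chaos_f0 = chaos_f0, reset_style = reset_style,
    mutate_all = isTRUE(mutate_all), swap_roles = isTRUE(swap_roles),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "teo_config")
}

.teo_eps <- 1e-12

#' One iterate of the sinusoidal chaotic map
#'
#' Advances the chaotic stream used by the dteo variant in place of uniform
#' draws: `f' = alpha * f^2 * sin(pi * f)`, reflected back into the open unit
#' interval (values >= 1 become `1 - eps`, values <= 0 become `eps`, with
#' `eps = 1e-12`) so the stream can never collapse or escape.
#'
#' @param f Current state in `(0, 1)`.
#' @param alpha Map gain in `(0, 4]`.
#' @return The next state, in `(0, 1)`.
#' @examples
#' chaos_next(0.5, 2.3) # 2.3 * 0.25 * sin(pi/2) = 0.575
#' @export
chaos_next <- function(f, alpha) {
  if (!is.finite(f) || f <= 0 || f >= 1)
    stop("chaotic state f must lie in the open interval (0, 1)", call. = FALSE)
  v <- alpha * f^2 * sin(pi * f)
  if (v >= 1) v <- 1 - .teo_eps
  if (v <= 0) v <- .teo_eps
  v
}

# Draw n values from the variant's random stream, advancing the chaotic state
# stored in `state` when the variant is dteo.
.teo_draw <- function(state, n, config) {
  if (config$variant == "dteo") {
    out <- numeric(n)
    f <- state$chaos_state
    for (i in seq_len(n)) {
      f <- chaos_next(f, config$chaos_alpha)
      out[i] <- f
    }
    state$chaos_state <- f
    list(values = out, state = state)
  } else {
    list(values = stats::runif(n), state = state)
  }
}

#' Cost ratio controlling the cooling rate of a candidate
#'
#' The per-candidate exponent of the Newton-cooling update: the candidate's
#' cost divided by the worst cost in the population, both already shifted to
#' be non-negative. Better candidates cool (move) more slowly.
#'
#' @param cost_i Shifted, non-negative cost of the candidate.
#' @param cost_worst Shifted cost of the worst candidate.
#' @return A ratio in `[0, 1]`; by convention 1 when `cost_worst` is 0
#'   (all-equal population).
#' @export
cost_ratio <- function(cost_i, cost_worst) {
  if (cost_worst == 0) return(1)
  cost_i / cost_worst
}

#' Initialize a thermal-exchange population
#'
#' Draws `population_size` candidate vectors uniformly inside the box
#' `[bounds_low, bounds_high]`; in the dteo variant the uniform variates are
#' taken from the chaotic stream. Costs are left unevaluated (`NA`).
#'
#' @param config A [teo_config()].
#' @return An object of class `"thermal_state"`: list with `temperatures`
#'   (matrix), `costs`, `memory`, `iteration`, `chaos_state`, `evaluations`.
#' @export
initialize_population <- function(config) {
  stopifnot(inherits(config, "teo_config"))
  f0 <- config$chaos_f0
  if (is.null(f0)) {
    # draw inside the basin of the map's chaotic attractor (~[0.49, 0.92]
    # for alpha = 2.3): orbits started below ~0.44 or above ~0.93 decay to
    # zero because alpha * f^2 * sin(pi * f) < f outside the band
    f0 <- 0.5 + 0.4 * stats::runif(1)
  }
  state <- list(temperatures = NULL, costs = NULL, memory = list(),
                iteration = 0L, chaos_state = f0, evaluations = 0L)
  class(state) <- "thermal_state"
  n <- config$population_size
  d <- config$dim
  dr <- .teo_draw(state, n * d, config)
  state <- dr$state
  u <- matrix(dr$values, n, d)
  span <- rep(config$bounds_high - config$bounds_low, each = n)
  state$temperatures <- matrix(rep(config$bounds_low, each = n), n, d) +
    u * matrix(span, n, d)
  state$costs <- rep(NA_real_, n)
  state
}

# Evaluate the objective on every row flagged by `which` (default: rows with
# NA cost); non-finite returns become +Inf with a warning.
.teo_evaluate <- function(state, objective, which = NULL) {
  if (is.null(which)) which <- which(is.na(state$costs))
  for (i in which) {
    v <- objective(state$temperatures[i, ])
    if (!is.finite(v) && !identical(v, Inf)) {
      # +Inf is a legitimate worst-cost sentinel (e.g. infeasible candidate)
      warning("objective returned a non-finite value; candidate assigned +Inf",
              call. = FALSE)
      v <- Inf
    }
    state$costs[i] <- v
    state$evaluations <- state$evaluations + 1L
  }
  state
}

# Merge the archive with the current population, keep the memory_size best
# ever, and overwrite the memory_size worst candidates with archive members.
.teo_memory_elitism <- function(state, config) {
  ms <- config$memory_size
  if (ms == 0L) return(state)
  cand_vec <- c(state$memory,
                lapply(seq_len(nrow(state$temperatures)), function(i)
                  list(vector = state$temperatures[i, ], cost = state$costs[i])))
  costs <- vapply(cand_vec, `[[`, numeric(1), "cost")
  keep <- order(costs)[seq_len(min(ms, length(cand_vec)))]
  state$memory <- cand_vec[keep]
  worst <- order(state$costs, decreasing = TRUE)[seq_len(min(ms, length(state$costs)))]
  for (k in seq_along(worst)) {
    if (k > length(state$memory)) break
    state$temperatures[worst[k], ] <- state$memory[[k]]$vector
    state$costs[worst[k]] <- state$memory[[k]]$cost
  }
  state
}

#' Multiplicative Gaussian mutation
#'
#' Perturbs each component as `x * (1 + decay * g)` with `g` standard normal.
#' A decay of 0 leaves the vector untouched; the optimizer draws
#' `decay = u * (1 - t)` with `u` uniform so the perturbation anneals over
#' the run.
#'
#' @param vector Numeric vector.
#' @param decay Scale in `[0, 1]`.
#' @return The mutated vector.
#' @export
gaussian_mutate <- function(vector, decay) {
  if (decay < 0 || decay > 1) stop("decay must lie in [0, 1]", call. = FALSE)
  vector * (1 + decay * stats::rnorm(length(vector)))
}

#' Advance a thermal-exchange population by one iteration
#'
#' Sorts the population by cost, pairs each cooling object (worse half) with
#' its environment object (better half), applies the environment
#' perturbation, the Newton-cooling move, the probabilistic one-dimension
#' reset and (dteo) the Gaussian mutation, clips to bounds, re-evaluates the
#' moved candidates and applies thermal-memory elitism.
#'
#' @param state A `"thermal_state"` with evaluated costs.
#' @param objective Function mapping an in-bounds vector to a finite scalar.
#' @param config A [teo_config()].
#' @return The updated state.
#' @export
teo_step <- function(state, objective, config) {
  stopifnot(inherits(state, "thermal_state"), inherits(config, "teo_config"))
  if (anyNA(state$costs)) state <- .teo_evaluate(state, objective)
  n <- config$population_size
  half <- n %/% 2L
  ord <- order(state$costs)              # stable: ties by candidate index
  state$temperatures <- state$temperatures[ord, , drop = FALSE]
  state$costs <- state$costs[ord]

  t_frac <- (state$iteration + 1L) / config$max_iterations
  fin <- is.finite(state$costs)
  base <- if (any(fin)) min(state$costs[fin]) else 0
  shifted <- state$costs - base + .teo_eps
  shifted[!is.finite(shifted)] <- if (any(fin))
    max(shifted[fin], .teo_eps) else .teo_eps
  worst <- max(shifted)
  gam <- vapply(shifted, cost_ratio, numeric(1), cost_worst = worst)

  cooling <- (half + 1L):n
  for (i in cooling) {
    j <- i - half
    # rnd/rand are random vectors (one draw per dimension)
    dr <- .teo_draw(state, config$dim, config); state <- dr$state
    r <- dr$values
    envp <- (1 - (config$m1 + config$m2 * (1 - t_frac)) * r) *
      state$temperatures[j, ]
    gi <- gam[i]
    newT <- envp + (state$temperatures[i, ] - envp) * exp(-gi * t_frac)
    if (stats::runif(1) < config$pr) {
      d <- sample.int(config$dim, 1L)
      dr <- .teo_draw(state, 1L, config); state <- dr$state
      span <- (config$bounds_high[d] - config$bounds_low[d]) * dr$values
      if (config$reset_style == "printed") span <- span * exp(-gi * t_frac)
      newT[d] <- config$bounds_low[d] + span
    }
    if (config$variant == "dteo") {
      decay <- stats::runif(1) * (1 - t_frac)
      newT <- gaussian_mutate(newT, decay)
    }
    state$temperatures[i, ] <- pmin(pmax(newT, config$bounds_low),
                                    config$bounds_high)
    state$costs[i] <- NA_real_
  }
  if (config$variant == "dteo" && config$mutate_all) {
    for (j in seq_len(half)) {
      decay <- stats::runif(1) * (1 - t_frac)
      newT <- gaussian_mutate(state$temperatures[j, ], decay)
      state$temperatures[j, ] <- pmin(pmax(newT, config$bounds_low),
                                      config$bounds_high)
      state$costs[j] <- NA_real_
    }
  }
  state <- .teo_evaluate(state, objective)
  state <- .teo_memory_elitism(state, config)
  state$iteration <- state$iteration + 1L
  state
}

#' Minimize an objective with TEO or dTEO
#'
#' Runs the full thermal-exchange loop: chaotic or uniform initialization,
#' `max_iterations` cooling sweeps with thermal-memory elitism, returning the
#' best-ever candidate.
#'
#' @param objective Function mapping an in-bounds numeric vector to a finite
#'   scalar cost.
#' @param config A [teo_config()].
#' @return An object of class `"teo_result"`: `best_vector`, `best_cost`,
#'   `history` (best-ever cost after each iteration), `evaluations`,
#'   `variant`, `config`.
#' @export
teo_minimize <- function(objective, config) {
  stopifnot(inherits(config, "teo_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- initialize_population(config)
  state <- .teo_evaluate(state, objective)
  best_i <- which.min(state$costs)
  best_cost <- state$costs[best_i]
  best_vector <- state$temperatures[best_i, ]
  history <- numeric(config$max_iterations)
  for (it in seq_len(config$max_iterations)) {
    state <- teo_step(state, objective, config)
    i <- which.min(state$costs)
    if (state$costs[i] < best_cost) {
      best_cost <- state$costs[i]
      best_vector <- state$temperatures[i, ]
    }
    history[it] <- best_cost
  }
  structure(list(best_vector = best_vector, best_cost = best_cost,
                 history = history, evaluations = state$evaluations,
                 variant = config$variant, config = config),
            class = "teo_result")
}

#' @export
print.teo_result <- function(x, ...) {
  cat(sprintf("%s minimization: best cost %.6g after %d evaluations\n",
              toupper(x$variant), x$best_cost, x$evaluations))
  cat("best vector:", format(x$best_vector, digits = 6), "\n")
  invisible(x)
}

#' @export
plot.teo_result <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "iteration", ylab = "best-ever cost",
                 main = sprintf("%s convergence", toupper(x$variant)), ...)
  invisible(x)
}
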