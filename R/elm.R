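# Evaluate `expr` under a temporary RNG seed, restoring the caller's stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Parameterized sigmoid activation
#'
#' `g(s) = 1 / (1 + exp(-(as * s + bs)))`, the activation whose per-neuron
#' `bs` parameter the optimizer tunes (`as` is held at 1). Overflow-safe for
#' large negative arguments.
#'
#' @param s Numeric input (the neuron pre-activation).
#' @param as_value,bs_value Activation shape parameters.
#' @return Values in `(0, 1)`.
#' @export
elm_sigmoid <- function(s, as_value = 1, bs_value = 0) {
  z <- as_value * s + bs_value
  ifelse(z >= 0, 1 / (1 + exp(-z)), exp(z) / (1 + exp(z)))
}

#' Hidden-layer output matrix of an ELM
#'
#' `H[n, m] = g(w_m' x_n + b_m)` with neuron m's activation parameter.
#'
#' @param model An `"elm"` model.
#' @param x Numeric matrix N x D.
#' @return Matrix N x M.
#' @export
elm_hidden <- function(model, x) {
  x <- as.matrix(x)
  if (!is.null(model$center))
    x <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  S <- sweep(x %*% t(model$input_weights), 2, model$biases, "+")
  Z <- sweep(model$as_value * S, 2, model$slopes, "+")
  ifelse(Z >= 0, 1 / (1 + exp(-Z)), exp(Z) / (1 + exp(Z)))
}

.elm_targets <- function(y) {
  y <- as.factor(y)
  if (nlevels(y) != 2L)
    stop("elm expects exactly two classes", call. = FALSE)
  T <- matrix(0, length(y), 2L, dimnames = list(NULL, levels(y)))
  T[cbind(seq_along(y), as.integer(y))] <- 1
  list(targets = T, levels = levels(y))
}

#' Fit an Extreme Learning Machine classifier
#'
#' Single-hidden-layer network: input weights and biases are drawn uniformly
#' on `(-1, 1)`, the hidden matrix `H` is formed through the sigmoid
#' activation, and the output weights solve the least-squares problem
#' `H beta = T` in closed form through the Moore-Penrose pseudoinverse,
#' where `T` one-hot encodes the two classes.
#'
#' @param x Numeric feature matrix N x D.
#' @param y Two-level factor (or coercible) of length N; the second level is
#'   conventionally the positive (melanoma) class.
#' @param hidden Number M of hidden neurons.
#' @param as_value Fixed multiplicative activation parameter.
#' @param slopes Optional length-M vector of per-neuron `bs` parameters;
#'   defaults to all ones (the unoptimized baseline).
#' @param standardize Center and scale feature columns before the random
#'   projection (stored in the model and applied at prediction);
#'   zero-variance columns are left uncentered at scale 1.
#' @param seed Optional seed for the random input layer; drawn under a local
#'   RNG so the caller's stream is unaffected.
#' @return Object of class `"elm"`.
#' @examples
#' x <- matrix(rnorm(40), 20)
#' y <- factor(rep(c("benign", "melanoma"), 10))
#' m <- elm(x, y, hidden = 10, seed = 1)
#' predict(m, x)
#' @export
elm <- function(x, y, hidden = 50L, as_value = 1, slopes = NULL, seed = NULL,
                standardize = TRUE) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite features", call. = FALSE)
  tg <- .elm_targets(y)
  hidden <- as.integer(hidden)
  if (hidden < 1L) stop("hidden must be >= 1", call. = FALSE)
  D <- ncol(x)
  ctr <- scl <- NULL
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    bad <- !is.finite(scl) | scl == 0
    ctr[bad] <- 0; scl[bad] <- 1
  }
  wb <- .with_seed(seed, list(
    w = matrix(stats::runif(hidden * D, -1, 1), hidden, D),
    b = stats::runif(hidden, -1, 1)))
  if (is.null(slopes)) slopes <- rep(1, hidden)
  stopifnot(length(slopes) == hidden)
  model <- structure(list(input_weights = wb$w, biases = wb$b,
                          slopes = as.numeric(slopes), as_value = as_value,
                          hidden = hidden, output_weights = NULL,
                          center = ctr, scale = scl,
                          levels = tg$levels, seed = seed),
                     class = "elm")
  H <- elm_hidden(model, x)
  model$output_weights <- MASS::ginv(H) %*% tg$targets
  colnames(model$output_weights) <- tg$levels
  model
}

#' Squared-error objective of a fitted network
#'
#' `E = (1/n) sum_i sum_j (d_ji - y_ji)^2` between one-hot targets `d` and
#' raw network outputs `y`; non-negative, zero iff the network reproduces
#' the targets exactly.
#'
#' @param model An `"elm"`.
#' @param x Feature matrix.
#' @param y Labels matching the model's classes.
#' @return Mean squared error over cases.
#' @export
elm_error <- function(model, x, y) {
  tg <- .elm_targets(factor(y, levels = model$levels))
  Y <- elm_hidden(model, as.matrix(x)) %*% model$output_weights
  sum((tg$targets - Y)^2) / nrow(Y)
}

#' Tune per-neuron activation parameters with dTEO
#'
#' Holds the randomly initialized input layer fixed and searches the
#' M-dimensional vector of per-neuron `bs` activation parameters with the
#' developed Thermal Exchange Optimization; each candidate refits the output
#' weights in closed form and is scored by the mean squared error between
#' one-hot targets and network outputs. The returned model is never worse
#' (in that error) than the all-ones baseline, which lies inside the search
#' space.
#'
#' @inheritParams elm
#' @param bs_bounds Length-2 box for every neuron's `bs`.
#' @param iterations dTEO iteration budget (published protocol: 700).
#' @param population dTEO population size.
#' @param seed Seed for both the input layer and the optimizer stream.
#' @return A fitted `"elm"` with optimized `slopes` and attributes
#'   `activation_error` (achieved E) and `baseline_error`.
#' @export
elm_optimize_activation <- function(x, y, hidden = 50L, as_value = 1,
                                    bs_bounds = c(-5, 5),
                                    iterations = 700L, population = 20L,
                                    seed = NULL) {
  x <- as.matrix(x)
  base <- elm(x, y, hidden = hidden, as_value = as_value, seed = seed)
  base_E <- elm_error(base, x, y)
  tg <- .elm_targets(y)
  score <- function(bs) {
    m <- base
    m$slopes <- bs
    H <- elm_hidden(m, x)
    beta <- MASS::ginv(H) %*% tg$targets
    sum((tg$targets - H %*% beta)^2) / nrow(H)
  }
  cfg <- teo_config(rep(bs_bounds[1], base$hidden),
                    rep(bs_bounds[2], base$hidden),
                    population_size = population,
                    max_iterations = iterations, variant = "dteo",
                    seed = seed)
  res <- teo_minimize(score, cfg)
  if (res$best_cost <= base_E) {
    best <- base
    best$slopes <- res$best_vector
    H <- elm_hidden(best, x)
    best$output_weights <- MASS::ginv(H) %*% tg$targets
    colnames(best$output_weights) <- tg$levels
    E <- res$best_cost
  } else {
    best <- base
    E <- base_E
  }
  attr(best, "activation_error") <- E
  attr(best, "baseline_error") <- base_E
  best
}

#' @export
predict.elm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (is.null(object$output_weights)) stop("unfitted model", call. = FALSE)
  newdata <- as.matrix(newdata)
  scores <- elm_hidden(object, newdata) %*% object$output_weights
  if (type == "score") return(scores)
  factor(object$levels[max.col(scores, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.elm <- function(x, ...) {
  cat(sprintf("ELM classifier: %d hidden neurons, classes %s vs %s%s\n",
              x$hidden, x$levels[1], x$levels[2],
              if (!is.null(attr(x, "activation_error")))
                sprintf(" (activation-optimized, E = %.4g)",
                        attr(x, "activation_error")) else ""))
  invisible(x)
}
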