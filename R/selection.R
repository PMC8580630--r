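#' Matthews-correlation fitness of a confusion table
#'
#' `(TP TN - FP FN) / sqrt((TN+FP)(TP+FP)(TP+FN)(TN+FN))`, the wrapper
#' selection objective; bounded in `[-1, 1]`, 1 for perfect classification,
#' -1 for total inversion, 0 by convention when any marginal sum is zero.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts, or a single list/vector
#'   with those names passed as `tp`.
#' @return The fitness value.
#' @examples
#' selection_fitness(50, 40, 10, 5)
#' @export
selection_fitness <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.list(tp) || (is.numeric(tp) && length(tp) == 4L && is.null(tn))) {
    cc <- as.list(tp); tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  }
  m <- c(tn + fp, tp + fp, tp + fn, tn + fn)
  if (any(m == 0)) return(0)
  (tp * tn - fp * fn) / sqrt(prod(m))
}

# Confusion counts with `positive` as the positive class.
.confusion <- function(truth, pred, positive) {
  list(tp = sum(pred == positive & truth == positive),
       tn = sum(pred != positive & truth != positive),
       fp = sum(pred == positive & truth != positive),
       fn = sum(pred != positive & truth == positive))
}

# Stratified k-fold assignment.
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in unique(y)) {
    ix <- sample(which(y == lv))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

#' Wrapper feature selection with dTEO
#'
#' Searches the unit hypercube `[0, 1]^p` with the developed Thermal
#' Exchange Optimization; a candidate vector selects the features whose
#' component exceeds 0.5, and its cost is one minus the mean k-fold
#' cross-validated Matthews correlation of an ELM trained on the selected
#' columns (empty selections score +Inf). Fitness evaluations are memoized
#' per selection so equal masks always score identically.
#'
#' @param x Numeric feature matrix (cases x features).
#' @param y Two-level class labels.
#' @param positive Positive-class label (defaults to the second factor
#'   level).
#' @param k Cross-validation folds.
#' @param hidden Hidden neurons of the inner ELM.
#' @param population,iterations dTEO budget.
#' @param seed Run seed (also fixes the inner ELM per fold so masks are
#'   compared under identical network draws).
#' @return Object of class `"feature_mask"`: logical `selected` named by
#'   feature, achieved `fitness`, and the optimizer `result`.
#' @export
select_features <- function(x, y, positive = NULL, k = 5L, hidden = 30L,
                            population = 20L, iterations = 50L,
                            seed = NULL) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(y) < 2L) stop("labels contain a single class", call. = FALSE)
  if (min(table(y)) < 2L) stop("need >= 2 cases per class", call. = FALSE)
  if (is.null(positive)) positive <- levels(y)[2]
  p <- ncol(x)
  folds <- .with_seed(if (is.null(seed)) NULL else seed + 1L,
                      .stratified_folds(y, k))
  cache <- new.env(parent = emptyenv())
  cv_fitness <- function(sel) {
    key <- paste(as.integer(sel), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    fits <- numeric(k)
    for (f in seq_len(k)) {
      tr <- folds != f
      m <- elm(x[tr, sel, drop = FALSE], y[tr], hidden = hidden,
               seed = if (is.null(seed)) f else seed + 100L + f)
      pred <- predict(m, x[!tr, sel, drop = FALSE])
      fits[f] <- selection_fitness(.confusion(y[!tr], pred, positive))
    }
    cache[[key]] <- mean(fits)
    cache[[key]]
  }
  objective <- function(v) {
    sel <- v > 0.5
    if (!any(sel)) return(Inf)
    1 - cv_fitness(sel)
  }
  cfg <- teo_config(rep(0, p), rep(1, p), population_size = population,
                    max_iterations = iterations, variant = "dteo",
                    seed = seed)
  res <- teo_minimize(objective, cfg)
  sel <- res$best_vector > 0.5
  if (!any(sel)) sel[which.max(res$best_vector)] <- TRUE  # never empty
  names(sel) <- colnames(x)
  structure(list(selected = sel, fitness = 1 - res$best_cost, result = res),
            class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("feature mask: %d/%d selected, CV fitness %.4f\n",
              sum(x$selected), length(x$selected), x$fitness))
  nm <- names(x$selected)
  if (!is.null(nm)) cat("  ", paste(nm[x$selected], collapse = ", "), "\n")
  invisible(x)
}
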