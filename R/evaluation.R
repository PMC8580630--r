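#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, positive predictive value `TP/(TP+FP)` and negative
#' predictive value `TN/(TN+FN)`. A metric with a zero denominator is
#' reported as `NaN` with a warning.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts, or a list with those
#'   names passed as `tp`.
#' @return Object of class `"metrics_report"`: the five metrics plus
#'   `counts`.
#' @examples
#' classification_metrics(9, 8, 1, 2)
#' @export
classification_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.list(tp)) { cc <- tp; tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn }
  total <- tp + tn + fp + fn
  if (total == 0) stop("no cases", call. = FALSE)
  ratio <- function(num, den, name) {
    if (den == 0) {
      warning(name, " undefined: zero denominator", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  structure(list(
    accuracy = (tp + tn) / total,
    sensitivity = ratio(tp, tp + fn, "sensitivity"),
    specificity = ratio(tn, tn + fp, "specificity"),
    ppv = ratio(tp, tp + fp, "ppv"),
    npv = ratio(tn, tn + fn, "npv"),
    counts = list(tp = tp, tn = tn, fp = fp, fn = fn)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.4f | sensitivity %.4f | specificity %.4f",
                     " | PPV %.4f | NPV %.4f\n"),
              x$accuracy, x$sensitivity, x$specificity, x$ppv, x$npv))
  cc <- x$counts
  cat(sprintf("counts: TP %d TN %d FP %d FN %d\n", cc$tp, cc$tn, cc$fp, cc$fn))
  invisible(x)
}

#' Repeated hold-out evaluation of the full classifier chain
#'
#' Implements the experimental protocol: for each repeat, a stratified
#' 80/20 train/test split, wrapper feature selection on the training set,
#' an activation-optimized ELM on the selected training features, and the
#' five metrics on the held-out test set. Reported metrics are means over
#' repeats; confusion counts are pooled.
#'
#' @param x Numeric feature matrix (cases x features).
#' @param y Two-level labels; `positive` defaults to `"melanoma"` when
#'   present, else the second level.
#' @param repeats Number of split repetitions (published protocol: 15).
#' @param train_frac Training fraction of each split.
#' @param select Logical: run wrapper feature selection per repeat.
#' @param select_iterations,select_population dTEO budget of the selection.
#' @param hidden Hidden neurons of the final ELM.
#' @param slope_iterations,slope_population dTEO budget of the activation
#'   search ([elm_optimize_activation()]); `slope_iterations = 0` skips it.
#' @param seed Base seed; repeat r derives its own sub-seed.
#' @return Object of class `"experiment_report"`: mean `metrics`, pooled
#'   `counts`, per-repeat data frame `per_repeat`, `repeats`.
#' @export
run_experiment <- function(x, y, repeats = 15L, train_frac = 0.8,
                           select = TRUE,
                           select_iterations = 50L, select_population = 20L,
                           hidden = 30L,
                           slope_iterations = 100L, slope_population = 20L,
                           seed = NULL) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("two classes required", call. = FALSE)
  positive <- if ("melanoma" %in% levels(y)) "melanoma" else levels(y)[2]
  rows <- vector("list", repeats)
  pooled <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (r in seq_len(repeats)) {
    rseed <- if (is.null(seed)) NULL else (seed + 1000L * r) %% .Machine$integer.max
    if (!is.null(rseed)) set.seed(rseed)
    tr <- logical(length(y))
    for (lv in levels(y)) {
      ix <- sample(which(y == lv))
      tr[ix[seq_len(max(1L, round(train_frac * length(ix))))]] <- TRUE
    }
    sel <- rep(TRUE, ncol(x))
    if (select) {
      fm <- select_features(x[tr, , drop = FALSE], y[tr], positive = positive,
                            hidden = hidden,
                            population = select_population,
                            iterations = select_iterations, seed = rseed)
      sel <- fm$selected
    }
    xt <- x[tr, sel, drop = FALSE]
    model <- if (slope_iterations > 0L) {
      elm_optimize_activation(xt, y[tr], hidden = hidden,
                              iterations = slope_iterations,
                              population = slope_population, seed = rseed)
    } else {
      elm(xt, y[tr], hidden = hidden, seed = rseed)
    }
    pred <- predict(model, x[!tr, sel, drop = FALSE])
    cc <- .confusion(y[!tr], pred, positive)
    m <- suppressWarnings(classification_metrics(cc))
    pooled <- pooled + unlist(cc)
    rows[[r]] <- data.frame(repeat_id = r, accuracy = m$accuracy,
                            sensitivity = m$sensitivity,
                            specificity = m$specificity,
                            ppv = m$ppv, npv = m$npv,
                            n_selected = sum(sel))
  }
  per_repeat <- do.call(rbind, rows)
  metrics <- colMeans(per_repeat[, c("accuracy", "sensitivity", "specificity",
                                     "ppv", "npv")], na.rm = TRUE)
  # prevalence identity: accuracy = (se*P + sp*N)/(P+N) on pooled counts
  structure(list(metrics = as.list(metrics),
                 counts = as.list(pooled),
                 per_repeat = per_repeat, repeats = repeats,
                 positive = positive),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("experiment (%d repeats, positive = %s):\n", x$repeats,
              x$positive))
  cat(sprintf(paste0("  mean accuracy %.4f | sensitivity %.4f |",
                     " specificity %.4f | PPV %.4f | NPV %.4f\n"),
              m$accuracy, m$sensitivity, m$specificity, m$ppv, m$npv))
  invisible(x)
}
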