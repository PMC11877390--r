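#' F1 score from precision and sensitivity
#'
#' The harmonic mean 2 * precision * sensitivity / (precision +
#' sensitivity). `NA` when either input is `NA` or both are zero.
#'
#' @param precision,sensitivity Fractions in \[0, 1\].
#' @return F1 as a fraction in \[0, 1\], or `NA`.
#' @export
f1_score <- function(precision, sensitivity) {
  ifelse(is.na(precision) | is.na(sensitivity) |
           precision + sensitivity == 0, NA_real_,
         2 * precision * sensitivity / (precision + sensitivity))
}

#' Binary classification metrics from confusion counts
#'
#' The five standard metrics: accuracy = (TP+TN)/(TP+FP+TN+FN), precision =
#' TP/(TP+FP), sensitivity = TP/(TP+FN), specificity = TN/(TN+FP) and
#' F1 = 2 * precision * sensitivity / (precision + sensitivity). Zero
#' denominators yield `NA` (undefined), never a division error.
#'
#' @param tp,fp,tn,fn Non-negative integer counts with positive class
#'   "alcohol": TP = true alcohol predicted alcohol, FP = true no-alcohol
#'   predicted alcohol, TN/FN their complements.
#' @return Named list `accuracy`, `precision`, `sensitivity`,
#'   `specificity`, `f1`, each a fraction in \[0, 1\] or `NA`.
#' @export
metrics_from_counts <- function(tp, fp, tn, fn) {
  for (v in list(tp = tp, fp = fp, tn = tn, fn = fn)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop_invalid("counts must be single non-negative numbers")
  }
  if (tp + fp + tn + fn == 0)
    stop_invalid("at least one count must be positive")
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- sdiv(tp, tp + fp)
  sensitivity <- sdiv(tp, tp + fn)
  list(accuracy = (tp + tn) / (tp + fp + tn + fn),
       precision = precision, sensitivity = sensitivity,
       specificity = sdiv(tn, tn + fp),
       f1 = f1_score(precision, sensitivity))
}

#' Round a fraction to an integer percent (half away from zero)
#'
#' Reported metrics use integer percents with halves rounded up
#' (0.865 -> 87), not banker's rounding.
#'
#' @param x Fraction in \[0, 1\] (or `NA`).
#' @return Integer percent (or `NA`).
#' @export
percent_round <- function(x) {
  ifelse(is.na(x), NA_integer_, as.integer(floor(x * 100 + 0.5)))
}

#' Confusion counts from true and predicted labels
#'
#' Rows are true labels, columns predicted — the convention used throughout
#' the package reports. For binary schemes the TP/FP/TN/FN scalars are
#' derived with "alcohol" as the positive class.
#'
#' @param truth,predicted Label vectors of equal length.
#' @param classes Ordered class labels (default: sorted union).
#' @param positive_class Positive class for the binary scalars.
#' @return A `confusion_counts`: list with `classes`, `counts` (true x
#'   predicted integer matrix), `row_percent`, and for two-class inputs
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted, classes = NULL,
                             positive_class = "alcohol") {
  if (length(truth) != length(predicted))
    stop_invalid("truth and predicted must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad))
    stop_invalid("labels outside `classes`: %s", paste(bad, collapse = ", "))
  tab <- table(factor(truth, classes), factor(predicted, classes))
  counts <- matrix(as.integer(tab), length(classes), length(classes),
                   dimnames = list(true = classes, predicted = classes))
  rs <- rowSums(counts)
  row_percent <- counts / ifelse(rs == 0, NA_real_, rs) * 100

  out <- list(classes = classes, counts = counts, row_percent = row_percent)
  if (length(classes) == 2L && positive_class %in% classes) {
    neg <- setdiff(classes, positive_class)
    out$tp <- counts[positive_class, positive_class]
    out$fn <- counts[positive_class, neg]
    out$fp <- counts[neg, positive_class]
    out$tn <- counts[neg, neg]
  }
  structure(out, class = "confusion_counts")
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores (predict positive
#' when score >= threshold) and integrates TPR over FPR by the trapezoidal
#' rule. Rank-based, so AUC is invariant under strictly increasing score
#' transforms.
#'
#' @param scores Numeric positive-class scores.
#' @param truth Binary labels.
#' @param positive_class The label counted as positive.
#' @return List with `points` (tibble: threshold, fpr, tpr) and `auc`.
#' @export
roc_curve <- function(scores, truth, positive_class = "alcohol") {
  if (length(scores) != length(truth))
    stop_invalid("scores and truth must have equal length")
  pos <- truth == positive_class
  if (!any(pos) || all(pos))
    stop_invalid("both classes must be present in `truth`")

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  np <- sum(pos); nn <- sum(!pos)
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / nn, numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Evaluate a trained model on a validation feature table
#'
#' Predicts every validation chunk, builds the confusion matrix (rows =
#' true, columns = predicted, with row-percentages as in the study's
#' confusion figures — note the per-label "accuracy" shown there is the
#' per-class recall), computes the five binary metrics when the scheme is
#' binary, and one-vs-rest ROC/AUC per class with a macro average.
#'
#' @param model A `trained_model` from [tune_and_train()].
#' @param validation Feature table containing the model's selected features
#'   and `time_label`.
#' @return An `evaluation_report`: list with `scheme`, `confusion`,
#'   `metrics` (fractions and rounded integer percents), `roc` (per class),
#'   `auc` (per class + macro), `n`, `accuracy`.
#' @export
evaluate_model <- function(model, validation) {
  if (!inherits(model, "trained_model"))
    stop_invalid("`model` must be a trained_model")
  miss <- setdiff(model$selected_features, names(validation))
  if (length(miss))
    stop_invalid("validation table lacks feature columns: %s",
                 paste(miss, collapse = ", "))
  scheme <- model$scheme
  truth <- apply_scheme(validation$time_label, scheme)
  prob <- predict(model, validation[, model$selected_features,
                                    drop = FALSE], type = "prob")
  pred <- colnames(prob)[max.col(prob, ties.method = "first")]

  # keep scheme class order, restricted to classes the model can emit
  classes <- intersect(scheme$classes, colnames(prob))
  conf <- confusion_counts(truth, pred, classes = classes,
                           positive_class = scheme$positive_class)
  accuracy <- sum(diag(conf$counts)) / sum(conf$counts)

  metrics <- NULL
  if (!is.na(scheme$positive_class) && !is.null(conf$tp)) {
    metrics <- metrics_from_counts(conf$tp, conf$fp, conf$tn, conf$fn)
    metrics$percent <- lapply(metrics, percent_round)
  }

  roc <- list(); auc <- list()
  for (cl in classes) {
    if (length(unique(truth == cl)) < 2L) next
    r <- roc_curve(prob[, cl], ifelse(truth == cl, cl, "rest"),
                   positive_class = cl)
    roc[[cl]] <- r$points
    auc[[cl]] <- r$auc
  }
  if (length(auc)) auc$macro <- mean(unlist(auc))

  structure(list(scheme = scheme, confusion = conf, metrics = metrics,
                 roc = roc, auc = auc, n = length(truth),
                 accuracy = accuracy),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report (%s scheme), n = %d chunks\n",
              x$scheme$name, x$n))
  cat(sprintf("  accuracy: %d%%\n", percent_round(x$accuracy)))
  cm <- x$confusion
  for (cl in cm$classes) {
    cells <- sprintf("%s %.0f%% (%d)", cm$classes,
                     cm$row_percent[cl, ], cm$counts[cl, ])
    cat(sprintf("  true %-14s -> %s\n", cl, paste(cells, collapse = ", ")))
  }
  if (!is.null(x$metrics))
    cat(sprintf(paste0("  precision %d%%, sensitivity %d%%, specificity ",
                       "%d%%, F1 %d%%\n"),
                x$metrics$percent$precision, x$metrics$percent$sensitivity,
                x$metrics$percent$specificity, x$metrics$percent$f1))
  if (length(x$auc))
    cat(sprintf("  AUC: %s\n",
                paste(sprintf("%s %.2f", names(x$auc),
                              unlist(x$auc)), collapse = ", ")))
  invisible(x)
}
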