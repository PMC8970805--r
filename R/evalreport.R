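# Confusion matrices and the classification metric suite (precision, recall,
# accuracy, F-score, Cohen's kappa), plus the repeated-iteration and
# per-subject report layouts.

#' Build a 2x2 confusion matrix
#'
#' Rows are the true class (left, right), columns the predicted class.
#'
#' @param true_labels,predicted_labels Equal-length vectors with values in
#'   \{0, 1\} or \{"left", "right"\}.
#' @return An object of class `confusion_matrix` (2x2 integer matrix).
#' @export
confusion <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    mi_stop("input", "label vectors differ in length")
  canon <- function(x) {
    if (is.numeric(x)) x <- c("left", "right")[x + 1]
    x <- as.character(x)
    if (!all(x %in% c("left", "right")))
      mi_stop("input", "labels must be 0/1 or left/right")
    factor(x, levels = c("left", "right"))
  }
  cm <- table(true = canon(true_labels), predicted = canon(predicted_labels))
  structure(matrix(as.integer(cm), 2, 2,
                   dimnames = list(true = c("left", "right"),
                                   predicted = c("left", "right"))),
            class = c("confusion_matrix", "matrix", "array"))
}

as_confusion <- function(cm) {
  if (inherits(cm, "confusion_matrix")) return(cm)
  cm <- as.matrix(cm)
  if (!all(dim(cm) == c(2, 2)) || any(cm < 0))
    mi_stop("input", "confusion matrix must be 2x2 and nonnegative")
  structure(matrix(as.numeric(cm), 2, 2,
                   dimnames = list(true = c("left", "right"),
                                   predicted = c("left", "right"))),
            class = c("confusion_matrix", "matrix", "array"))
}

#' Classification metrics from a 2x2 confusion matrix
#'
#' With the left class as positive: precision TP/(TP+FP), recall TP/(TP+FN),
#' accuracy (TP+TN)/total, F-score the harmonic mean of precision and recall,
#' and Cohen's kappa `(p_o - p_e)/(1 - p_e)` with chance agreement from the
#' marginal products. Raw proportions are retained; `$percent` carries the
#' same values as percentages rounded half-up to 2 decimals for display.
#'
#' @param cm A [confusion()] matrix (or any 2x2 matrix, rows = truth).
#' @param positive Positive class, `"left"` (default) or `"right"`.
#' @return An object of class `classification_metrics`: list with `precision`,
#'   `recall`, `accuracy`, `f_score`, `kappa` (raw, in \[0, 1\] or \[-1, 1\]
#'   for kappa) and `percent` (named vector, 2-decimal percentages).
#' @export
metrics_from_cm <- function(cm, positive = "left") {
  cm <- as_confusion(cm)
  positive <- match.arg(positive, c("left", "right"))
  i <- if (positive == "left") 1 else 2
  tp <- cm[i, i]; fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp; tn <- sum(cm) - tp - fn - fp
  total <- sum(cm)
  if (total == 0) mi_stop("input", "empty confusion matrix")
  if (tp + fp == 0) {
    mi_warn("degenerate", "no predicted positives; precision reported as 0")
    precision <- 0
  } else precision <- tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  accuracy <- (tp + tn) / total
  f_score <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  p_o <- accuracy
  p_e <- (sum(cm[1, ]) * sum(cm[, 1]) + sum(cm[2, ]) * sum(cm[, 2])) / total^2
  kappa <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)
  raw <- list(precision = precision, recall = recall, accuracy = accuracy,
              f_score = f_score, kappa = kappa)
  structure(c(raw, list(
    percent = vapply(raw, function(v) round_half_up(100 * v, 2), 0),
    cm = cm, positive = positive)),
    class = "classification_metrics")
}

# round half away from zero at `digits` decimals (display convention;
# base round() rounds half to even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("precision %.2f%%  recall %.2f%%  accuracy %.2f%%  F %.2f%%  kappa %.2f%%\n",
              x$percent["precision"], x$percent["recall"], x$percent["accuracy"],
              x$percent["f_score"], x$percent["kappa"]))
  invisible(x)
}

#' Metric table over repeated iterations, with an average row
#'
#' @param metrics_list List of [metrics_from_cm()] results.
#' @return Data frame with one row per iteration plus an `Average` row
#'   (arithmetic mean of the per-iteration percentages).
#' @export
iteration_report <- function(metrics_list) {
  rows <- do.call(rbind, lapply(metrics_list, function(m)
    as.data.frame(as.list(m$percent))))
  names(rows) <- c("precision", "recall", "accuracy", "f_score", "kappa")
  avg <- as.data.frame(lapply(rows, function(col) round_half_up(mean(col), 2)))
  out <- rbind(rows, avg)
  out <- cbind(iteration = c(paste0("Iteration-", seq_len(nrow(rows))),
                             "Average"), out)
  rownames(out) <- NULL
  out
}

#' Per-subject, per-run accuracy table with marginal means
#'
#' @param accuracies Numeric matrix (runs x subjects), values in \[0, 100\].
#' @return List with `table` (the input with an Avg column and Avg row),
#'   `run_means`, `subject_means`, `grand_mean` (2-decimal rounded).
#' @export
subject_report <- function(accuracies) {
  if (is.data.frame(accuracies)) accuracies <- as.matrix(accuracies)
  if (!is.matrix(accuracies) || any(!is.finite(accuracies)))
    mi_stop("shape", "accuracies must be a finite numeric matrix (runs x subjects)")
  if (any(accuracies < 0 | accuracies > 100))
    mi_stop("shape", "accuracies must lie in [0, 100]")
  run_means <- round_half_up(rowMeans(accuracies), 2)
  subject_means <- round_half_up(colMeans(accuracies), 2)
  grand <- round_half_up(mean(accuracies), 2)
  tab <- rbind(cbind(accuracies, Avg = run_means),
               Avg = c(subject_means, grand))
  list(table = tab, run_means = run_means, subject_means = subject_means,
       grand_mean = grand)
}
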