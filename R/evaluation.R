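#' Confusion counts and derived metrics
#'
#' SEM (label 1) is the positive class. Returns counts and the four
#' metrics as percentages: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' accuracy `(TP+TN)/n`, and `F1 = 2PR/(P+R)`.
#'
#' @param y_true,y_pred binary vectors of equal, non-zero length.
#' @return an `EvalReport` list: `TP`, `TN`, `FP`, `FN`, `n_pos`, `n_neg`,
#'   `precision`, `recall`, `accuracy`, `f1` (percentages).
#' @export
confusionMetrics <- function(y_true, y_pred) {
  stopIfNot(length(y_true) == length(y_pred), "length mismatch")
  stopIfNot(length(y_true) > 0, "empty input")
  stopIfNot(all(y_true %in% c(0, 1)) && all(y_pred %in% c(0, 1)),
            "labels must be binary")
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  reportFromCounts(n_pos = tp + fn, n_neg = tn + fp, fp = fp, fn = fn)
}

#' Build an evaluation report from test-set counts
#'
#' Reconstructs the full metric set from the positive/negative sample
#' counts and the error counts, as reported in per-subject results tables.
#'
#' @param n_pos,n_neg positive (SEM) and negative test sample counts.
#' @param fp,fn false positive and false negative counts.
#' @return an `EvalReport` list (see [confusionMetrics()]).
#' @export
reportFromCounts <- function(n_pos, n_neg, fp, fn) {
  tp <- n_pos - fn
  tn <- n_neg - fp
  stopIfNot(tp >= 0 && tn >= 0, "counts inconsistent")
  precision <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
  recall <- if (n_pos == 0) 0 else 100 * tp / (tp + fn)
  accuracy <- 100 * (tp + tn) / (n_pos + n_neg)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 n_pos = n_pos, n_neg = n_neg,
                 precision = precision, recall = recall,
                 accuracy = accuracy, f1 = f1),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport: %d pos / %d neg, FP=%d FN=%d\n",
              x$n_pos, x$n_neg, x$FP, x$FN))
  cat(sprintf("  precision %.2f%%  recall %.2f%%  accuracy %.2f%%  F1 %.2f%%\n",
              x$precision, x$recall, x$accuracy, x$f1))
  invisible(x)
}

#' Precision-recall curve and average precision
#'
#' Precision and recall over all score thresholds (descending), with the
#' area computed by the average-precision step rule
#' `AP = sum_n (R_n - R_{n-1}) P_n`. The area is invariant to strictly
#' monotone transforms of the scores.
#'
#' @param y_true binary truth vector.
#' @param scores positive-class (SEM) probabilities or scores.
#' @return list with `recall`, `precision`, `thresholds` and `auc`.
#' @export
prCurve <- function(y_true, scores) {
  stopIfNot(length(y_true) == length(scores), "length mismatch")
  if (length(unique(y_true)) < 2)
    stop("PR curve undefined for single-class truth", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]
  s <- scores[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  # collapse tied scores: evaluate at the last index of each tie group
  keep <- c(diff(s) < 0, TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  npos <- sum(y_true == 1)
  precision <- tp / (tp + fp)
  recall <- tp / npos
  auc <- sum(diff(c(0, recall)) * precision)
  list(recall = recall, precision = precision, thresholds = s[keep],
       auc = auc)
}

#' Aggregate evaluation reports
#'
#' Per-metric mean and standard deviation over subjects, rounded to two
#' decimals. The SD convention matches published per-subject tables
#' (population, n denominator) by default; the sample convention (n-1) is
#' available via `sd_type`.
#'
#' @param reports list of at least two `EvalReport`s.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return data.frame with one row per metric: `mean` and `sd`.
#' @export
aggregateReports <- function(reports, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopIfNot(length(reports) >= 2, "need at least two reports")
  metrics <- c("FP", "FN", "precision", "recall", "accuracy", "f1")
  sdFun <- function(x) {
    s <- stats::sd(x)
    if (sd_type == "population") s * sqrt((length(x) - 1) / length(x)) else s
  }
  out <- data.frame(metric = metrics,
                    mean = vapply(metrics, function(m)
                      round(mean(vapply(reports, `[[`, 0, m)), 2), 0),
                    sd = vapply(metrics, function(m)
                      round(sdFun(vapply(reports, `[[`, 0, m)), 2), 0))
  rownames(out) <- NULL
  out
}

#' Evaluate a trained model on held-out windows
#'
#' Inference-mode predictions (argmax of the probability pair) scored
#' against the true labels.
#'
#' @param model a trained [SemModel-class].
#' @param ws a [SemWindowSet-class].
#' @param idx window indices to evaluate (e.g. the test portion of
#'   [chronologicalSplit()]).
#' @return list with `report` (an `EvalReport`), `probs` and `pred`.
#' @export
evaluateModel <- function(model, ws, idx = seq_len(ncol(ws))) {
  probs <- predictProb(model, ws, idx)
  pred <- max.col(probs) - 1L
  list(report = confusionMetrics(ws$label[idx], pred),
       probs = probs, pred = pred)
}
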