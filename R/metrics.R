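#' Area under the ROC curve by the rank statistic
#'
#' Computes AUCROC as the Mann-Whitney statistic on midranks: the
#' probability that a randomly chosen positive scores above a randomly
#' chosen negative, with ties counting one half. Invariant under any
#' strictly increasing transform of the scores.
#'
#' @param y_true Logical (or 0/1) labels.
#' @param y_score Numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(y_true, y_score) {
  y_true <- as.logical(y_true)
  stopifnot(length(y_true) == length(y_score), !anyNA(y_true),
            !anyNA(y_score))
  n_pos <- sum(y_true)
  n_neg <- sum(!y_true)
  if (n_pos == 0 || n_neg == 0)
    stop("AUCROC undefined: y_true has a single class", call. = FALSE)
  r <- rank(y_score, ties.method = "average")
  (sum(r[y_true]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion-matrix metrics and AUCROC
#'
#' Thresholds the scores at `threshold` and reports the six evaluation
#' metrics: accuracy, sensitivity, specificity, recall, and precision
#' as percentages, and AUCROC on the probability scale. Sensitivity
#' and recall are the same quantity (true positives over all actual
#' positives); both are reported.
#'
#' @param y_true Logical (or 0/1) labels.
#' @param y_score Numeric scores in any monotone scale.
#' @param threshold Decision threshold on the scores (default 0.5).
#' @return List with `accuracy`, `sensitivity`, `specificity`,
#'   `recall`, `precision` (percentages), `aucroc`, and the confusion
#'   counts `tp`, `fp`, `tn`, `fn`.
#' @examples
#' compute_metrics(c(TRUE, TRUE, FALSE), c(0.9, 0.4, 0.1))
#' @export
compute_metrics <- function(y_true, y_score, threshold = 0.5) {
  y_true <- as.logical(y_true)
  stopifnot(length(y_true) == length(y_score))
  pred <- y_score >= threshold
  tp <- sum(pred & y_true)
  fp <- sum(pred & !y_true)
  tn <- sum(!pred & !y_true)
  fn <- sum(!pred & y_true)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  list(accuracy = 100 * (tp + tn) / length(y_true),
       sensitivity = sens, specificity = spec,
       recall = sens, precision = prec,
       aucroc = auc_roc(y_true, y_score),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' ROC curve points
#'
#' False and true positive rates over all score thresholds, for curve
#' export.
#' @param y_true Logical labels.
#' @param y_score Numeric scores.
#' @return Data frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(y_true, y_score) {
  y_true <- as.logical(y_true)
  ord <- order(y_score, decreasing = TRUE)
  tpr <- cumsum(y_true[ord]) / sum(y_true)
  fpr <- cumsum(!y_true[ord]) / sum(!y_true)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}
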