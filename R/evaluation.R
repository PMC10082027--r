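#' Confusion matrix
#'
#' @param true_labels,predicted_labels integer vectors with values in
#'   `[0, K)`.
#' @param K number of classes.
#' @return `K x K` integer matrix of counts; rows are true classes,
#'   columns predicted classes.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, K) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  if (any(true_labels < 0 | true_labels >= K) ||
      any(predicted_labels < 0 | predicted_labels >= K))
    stop("labels must lie in [0, K)")
  cm <- matrix(0L, K, K,
               dimnames = list(true = paste0("Grade", 0:(K - 1)),
                               predicted = paste0("Grade", 0:(K - 1))))
  for (i in seq_along(true_labels))
    cm[true_labels[i] + 1L, predicted_labels[i] + 1L] <-
      cm[true_labels[i] + 1L, predicted_labels[i] + 1L] + 1L
  cm
}

# one-vs-rest marginal counts for class k (1-based)
.ovr_counts <- function(cm, k) {
  tp <- cm[k, k]
  fn <- sum(cm[k, ]) - tp
  fp <- sum(cm[, k]) - tp
  tn <- sum(cm) - tp - fn - fp
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

.safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Per-class one-vs-rest metrics
#'
#' For each class: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1
#' `2TP/(2TP+FP+FN)` and one-vs-rest accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`.  A zero denominator yields 0 and sets the
#' `degenerate` flag for that class.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @return data frame with one row per class and columns `class`,
#'   `precision`, `recall`, `f1`, `accuracy`, `support`, `degenerate`.
#' @export
per_class_metrics <- function(cm) {
  K <- nrow(cm)
  rows <- lapply(seq_len(K), function(k) {
    ct <- .ovr_counts(cm, k)
    data.frame(
      class = k - 1L,
      precision = .safe_div(ct$tp, ct$tp + ct$fp),
      recall = .safe_div(ct$tp, ct$tp + ct$fn),
      f1 = .safe_div(2 * ct$tp, 2 * ct$tp + ct$fp + ct$fn),
      accuracy = .safe_div(ct$tp + ct$tn, ct$tp + ct$tn + ct$fp + ct$fn),
      support = ct$tp + ct$fn,
      degenerate = (ct$tp + ct$fp == 0) || (ct$tp + ct$fn == 0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overall metrics
#'
#' Overall accuracy is micro: the trace of the confusion matrix over the
#' total count (equivalently, pooled one-vs-rest counts — not the average
#' of the per-class accuracies).  Overall precision, recall and F1 are
#' reported macro-averaged (unweighted mean over classes); micro and
#' support-weighted versions are included for transparency.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @return list with `accuracy`, `precision`, `recall`, `f1` (macro) and
#'   sub-lists `micro` and `weighted`.
#' @export
overall_metrics <- function(cm) {
  pc <- per_class_metrics(cm)
  total <- sum(cm)
  acc <- sum(diag(cm)) / total
  wts <- pc$support / sum(pc$support)
  list(accuracy = acc,
       precision = mean(pc$precision),
       recall = mean(pc$recall),
       f1 = mean(pc$f1),
       micro = list(precision = acc, recall = acc, f1 = acc),
       weighted = list(precision = sum(wts * pc$precision),
                       recall = sum(wts * pc$recall),
                       f1 = sum(wts * pc$f1)))
}

#' Full metrics report
#'
#' @param true_labels,predicted_labels 0-based label vectors.
#' @param K number of classes.
#' @param proba optional `N x K` probability matrix; when supplied,
#'   one-vs-rest ROC-AUC values are included.
#' @param digits rounding applied to the per-class table (4, matching the
#'   reporting precision of the grading study tables).
#' @return list with `confusion`, `per_class` (rounded), `overall`, and
#'   optionally `auc`.
#' @export
metrics_report <- function(true_labels, predicted_labels, K, proba = NULL,
                           digits = 4L) {
  cm <- confusion_matrix(true_labels, predicted_labels, K)
  pc <- per_class_metrics(cm)
  num <- c("precision", "recall", "f1", "accuracy")
  pc[num] <- lapply(pc[num], round, digits = digits)
  out <- list(confusion = cm, per_class = pc, overall = overall_metrics(cm))
  if (!is.null(proba)) out$auc <- roc_auc_ovr(true_labels, proba, K)
  out
}

#' One-vs-rest ROC-AUC
#'
#' For every class `k`, the AUC of score column `k` against the indicator
#' `true == k`, computed with the rank (Mann-Whitney) formulation with
#' ties averaged; the mean is the unweighted average over classes with
#' defined AUC.  A class absent from the truth (or covering all of it)
#' has undefined AUC, reported as `NA` and excluded from the mean.
#'
#' @param true_labels 0-based label vector.
#' @param probability_matrix `N x K` matrix whose rows sum to 1.
#' @param K number of classes.
#' @return list with `per_class` (length-`K` vector, `NA` where
#'   undefined) and `mean`.
#' @export
roc_auc_ovr <- function(true_labels, probability_matrix, K) {
  probability_matrix <- rbind(probability_matrix)
  if (any(abs(rowSums(probability_matrix) - 1) > 1e-6))
    warning("probability rows do not sum to 1")
  auc <- vapply(seq_len(K), function(k) {
    pos <- true_labels == (k - 1L)
    n1 <- sum(pos)
    n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(probability_matrix[, k])  # ties get average ranks
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  if (anyNA(auc))
    warning("AUC undefined for ", sum(is.na(auc)),
            " class(es) absent from the truth; excluded from the mean")
  list(per_class = auc, mean = mean(auc, na.rm = TRUE))
}
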