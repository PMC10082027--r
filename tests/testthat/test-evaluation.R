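# Confusion matrices, one-vs-rest metrics and ROC-AUC.

test_that("confusion_matrix counts pairs correctly", {
  cm <- confusion_matrix(0:4, 0:4, 5)
  expect_equal(diag(cm), setNames(rep(1L, 5), paste0("Grade", 0:4)))
  expect_equal(sum(cm), 5)

  cm <- confusion_matrix(c(0, 1, 2), c(0, 0, 0), 3)
  expect_equal(sum(cm[, 1]), 3)
  expect_equal(sum(cm[, -1]), 0)

  # six labelled pairs enumerated by hand
  truth <- c(0, 0, 1, 1, 2, 2)
  pred  <- c(0, 1, 1, 1, 0, 2)
  cm <- confusion_matrix(truth, pred, 3)
  expect_equal(unname(cm),
               rbind(c(1L, 1L, 0L), c(0L, 2L, 0L), c(1L, 0L, 1L)))
  expect_error(confusion_matrix(c(0, 5), c(0, 0), 5), "\\[0, K\\)")
})

test_that("per-class metrics reproduce the grading-study worked examples", {
  # Grade-0 with support 41 and 40 correct: recall = 40/41 = 0.9756
  cm <- matrix(0L, 5, 5)
  cm[1, 1] <- 40L; cm[1, 2] <- 1L   # one grade-0 patch missed
  cm[2, 1] <- 1L                    # one false positive into grade 0
  cm[2, 2] <- 26L; cm[3, 3] <- 25L; cm[4, 4] <- 24L; cm[5, 5] <- 28L
  pc <- per_class_metrics(cm)
  expect_equal(round(pc$recall[1], 4), 0.9756)
  # TP=40, FP=1, FN=1: F1 = 80/82 = 0.9756
  expect_equal(round(pc$f1[1], 4), 0.9756)
  expect_equal(pc$support[1], 41)
})

test_that("degenerate classes yield 0 with a flag", {
  cm <- matrix(0L, 3, 3)
  cm[1, 1] <- 5L; cm[2, 2] <- 5L  # class 2 absent
  pc <- per_class_metrics(cm)
  expect_equal(pc$recall[3], 0)
  expect_true(pc$degenerate[3])
  expect_false(any(pc$degenerate[1:2]))
})

test_that("overall metrics use micro accuracy and macro averaging", {
  # unweighted mean of the published per-class precisions is 0.8978
  prec <- c(0.9756, 0.8846, 0.9047, 0.7241, 1)
  expect_equal(round(mean(prec), 4), 0.8978)

  # perfect predictions: every metric is 1
  cm <- diag(c(10L, 5L, 7L))
  om <- overall_metrics(cm)
  expect_equal(om$accuracy, 1)
  expect_equal(om$precision, 1)
  expect_equal(om$f1, 1)

  # hand-computed 2-class case
  cm <- matrix(c(3L, 2L, 1L, 4L), 2, 2)  # rows true, cols predicted
  om <- overall_metrics(cm)
  expect_equal(om$accuracy, 0.7)
  expect_equal(om$precision, mean(c(3 / 5, 4 / 5)))
})

test_that("micro-averaged precision and recall equal overall accuracy", {
  set.seed(8)
  for (i in 1:5) {
    truth <- sample(0:3, 60, replace = TRUE)
    pred <- ifelse(runif(60) < 0.6, truth, sample(0:3, 60, replace = TRUE))
    cm <- confusion_matrix(truth, pred, 4)
    om <- overall_metrics(cm)
    expect_equal(om$micro$precision, om$accuracy)
    expect_equal(om$micro$recall, om$accuracy)
  }
})

test_that("consistent class permutation permutes per-class metrics only", {
  set.seed(9)
  truth <- sample(0:2, 50, replace = TRUE)
  pred <- sample(0:2, 50, replace = TRUE)
  perm <- c(2L, 0L, 1L)
  om1 <- overall_metrics(confusion_matrix(truth, pred, 3))
  om2 <- overall_metrics(confusion_matrix(perm[truth + 1], perm[pred + 1], 3))
  expect_equal(om1$accuracy, om2$accuracy)
  expect_equal(om1$precision, om2$precision)
  pc1 <- per_class_metrics(confusion_matrix(truth, pred, 3))
  pc2 <- per_class_metrics(confusion_matrix(perm[truth + 1], perm[pred + 1], 3))
  # old class l becomes class perm[l + 1]: rows permute accordingly
  expect_equal(pc2$recall[perm + 1], pc1$recall)
  expect_equal(pc2$f1[perm + 1], pc1$f1)
})

test_that("ROC-AUC: perfect separation gives 1, rank formulation is exact", {
  # perfectly separating scores
  truth <- c(0, 0, 1, 1, 2, 2)
  proba <- rbind(c(.8, .1, .1), c(.9, .05, .05), c(.1, .8, .1),
                 c(.2, .7, .1), c(.1, .1, .8), c(.05, .05, .9))
  auc <- roc_auc_ovr(truth, proba, 3)
  expect_equal(auc$per_class, rep(1, 3))
  expect_equal(auc$mean, 1)

  # 4-point toy set against a brute-force over-thresholds oracle
  truth <- c(1, 0, 1, 0)
  s <- c(0.9, 0.8, 0.4, 0.2)
  proba <- cbind(1 - s, s)
  brute_auc <- function(score, pos) {
    # trapezoidal area over all threshold-induced (FPR, TPR) points
    th <- sort(unique(c(-Inf, score, Inf)), decreasing = TRUE)
    tpr <- vapply(th, function(t) mean(score[pos] >= t), numeric(1))
    fpr <- vapply(th, function(t) mean(score[!pos] >= t), numeric(1))
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  expect_equal(roc_auc_ovr(truth, proba, 2)$per_class[2],
               brute_auc(s, truth == 1))
})

test_that("ROC-AUC agrees with an independent implementation and is rank-invariant", {
  skip_if_not_installed("pROC")
  set.seed(10)
  truth <- sample(0:2, 40, replace = TRUE)
  raw <- matrix(runif(120), 40)
  proba <- raw / rowSums(raw)
  ours <- roc_auc_ovr(truth, proba, 3)
  for (k in 1:3) {
    ref <- as.numeric(pROC::auc(pROC::roc(
      as.integer(truth == k - 1), proba[, k], quiet = TRUE,
      direction = "<")))
    expect_equal(ours$per_class[k], ref, tolerance = 1e-10)
  }
  # strictly monotone transform of one column leaves its AUC unchanged
  proba2 <- proba
  proba2[, 1] <- exp(3 * proba2[, 1])
  a2 <- suppressWarnings(roc_auc_ovr(truth, proba2, 3))
  expect_equal(a2$per_class[1], ours$per_class[1])
})

test_that("uninformative scores give AUC near 0.5 at large n", {
  set.seed(11)
  n <- 4000
  truth <- sample(0:4, n, replace = TRUE)
  raw <- matrix(runif(5 * n), n)
  proba <- raw / rowSums(raw)
  auc <- roc_auc_ovr(truth, proba, 5)
  expect_true(all(abs(auc$per_class - 0.5) < 0.05))
  expect_lt(abs(auc$mean - 0.5), 0.05)
})

test_that("a class absent from the truth is flagged and excluded", {
  truth <- c(0, 0, 1, 1)
  proba <- matrix(1 / 3, 4, 3)
  expect_warning(auc <- roc_auc_ovr(truth, proba, 3), "undefined")
  expect_true(is.na(auc$per_class[3]))
  expect_false(is.na(auc$mean))
})

test_that("metrics_report bundles and rounds to 4 decimals", {
  truth <- c(0, 0, 0, 1, 1, 2)
  pred <- c(0, 0, 1, 1, 1, 2)
  rep <- metrics_report(truth, pred, 3)
  expect_equal(rep$per_class$recall[1], round(2 / 3, 4))
  expect_equal(rep$overall$accuracy, 5 / 6)
  expect_s3_class(rep$per_class, "data.frame")
})
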