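#' Stratified K-fold assignment
#'
#' Shuffles indices within each class under the seed and deals them
#' round-robin across folds (rotating the starting fold between
#' classes to balance fold sizes), so every fold's class count differs
#' from the proportional share by less than one sample.
#'
#' @param labels class labels (any number of classes).
#' @param K number of folds (>= 2); every class must have >= K samples.
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..K, one per sample.
#' @examples
#' table(stratifiedFolds(rep(c("a", "b"), each = 50), K = 10, seed = 1))
#' @export
stratifiedFolds <- function(labels, K, seed = 1) {
  stopIf(K < 2, "K must be >= 2")
  labels <- as.character(labels)
  counts <- table(labels)
  small <- names(counts)[counts < K]
  stopIf(length(small) > 0,
         "class(es) with fewer than K=%d samples: %s", K,
         paste(small, collapse = ", "))
  fold <- integer(length(labels))
  withSeed(seed, {
    offset <- 0L
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      idx <- idx[sample(length(idx))]
      fold[idx] <- (seq_along(idx) - 1L + offset) %% K + 1L
      offset <- (offset + length(idx)) %% K
    }
  })
  fold
}

#' Confusion counts for a binary task
#'
#' @param truth,pred factors (or characters) over the same two levels.
#' @param positive label counted as positive.
#' @return list of class \code{"ConfusionCounts"} with TP, FP, FN, TN.
#' @export
confusionCounts <- function(truth, pred, positive) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopIf(length(truth) != length(pred), "truth and pred lengths differ")
  stopIf(length(truth) == 0L, "empty prediction set")
  structure(list(TP = sum(truth == positive & pred == positive),
                 FP = sum(truth != positive & pred == positive),
                 FN = sum(truth == positive & pred != positive),
                 TN = sum(truth != positive & pred != positive)),
            class = "ConfusionCounts")
}

metricTriplet <- function(TP, FP, FN) {
  flags <- character(0)
  precision <- if (TP + FP == 0) { flags <- c(flags, "precision"); 0 }
               else TP / (TP + FP)
  recall <- if (TP + FN == 0) { flags <- c(flags, "recall"); 0 }
            else TP / (TP + FN)
  f1 <- if (precision + recall == 0) { flags <- c(flags, "f1"); 0 }
        else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1, flags = flags)
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' accuracy = (TP + TN) / (TP + FP + FN + TN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = harmonic mean of precision and recall.
#' Macro averaging (the default) averages precision/recall/F1 over the
#' positive and negative class; positive-class averaging reports them
#' for the positive class only. Zero-denominator ratios are reported as
#' 0 and flagged in attribute \code{"undefined"}.
#'
#' @param counts a [confusionCounts()] result.
#' @param averaging "macro" or "positive_class".
#' @return list of class \code{"MetricSet"} with accuracy, precision,
#'   recall, f1 and averaging.
#' @examples
#' computeMetrics(structure(list(TP = 3, FP = 1, FN = 1, TN = 5),
#'                          class = "ConfusionCounts"), "positive_class")
#' @export
computeMetrics <- function(counts,
                           averaging = c("macro", "positive_class")) {
  averaging <- match.arg(averaging)
  stopIf(!inherits(counts, "ConfusionCounts"),
         "counts must come from confusionCounts()")
  total <- counts$TP + counts$FP + counts$FN + counts$TN
  stopIf(total == 0, "total count must be positive")
  acc <- (counts$TP + counts$TN) / total
  pos <- metricTriplet(counts$TP, counts$FP, counts$FN)
  if (averaging == "positive_class") {
    out <- list(accuracy = acc, precision = pos$precision,
                recall = pos$recall, f1 = pos$f1, averaging = averaging)
    flags <- pos$flags
  } else {
    neg <- metricTriplet(counts$TN, counts$FN, counts$FP)
    out <- list(accuracy = acc,
                precision = (pos$precision + neg$precision) / 2,
                recall = (pos$recall + neg$recall) / 2,
                f1 = (pos$f1 + neg$f1) / 2, averaging = averaging)
    flags <- unique(c(pos$flags, neg$flags))
  }
  class(out) <- "MetricSet"
  attr(out, "undefined") <- flags
  out
}

#' @export
print.MetricSet <- function(x, ...) {
  cat(sprintf(
    "MetricSet (%s): accuracy %.4f, precision %.4f, recall %.4f, F1 %.4f\n",
    x$averaging, x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Stratified K-fold cross-validation of an SVM ensemble
#'
#' Maps labels onto the task, assigns stratified folds, trains one
#' ensemble per fold on the other K-1 folds and scores the held-out
#' fold, so every retained sample is scored exactly once. Pooled
#' metrics are computed over the union of validation predictions.
#'
#' @param X feature matrix aligned with \code{labels}.
#' @param labels three-class labels.
#' @param task a [taskSpec()] or shorthand.
#' @param spec an [ensembleSpec()]; defaults to task defaults (the
#'   fold seed is derived from \code{seed}, not from the spec).
#' @param K fold count (default 10).
#' @param seed integer seed controlling folds and member training.
#' @param averaging metric averaging mode.
#' @return list of class \code{"CVReport"}: K, task, fold assignment
#'   (over retained rows), per-fold [computeMetrics()] sets, pooled
#'   metrics, pooled confusion counts, fold ensembles and the pooled
#'   prediction data.frame.
#' @export
crossValidate <- function(X, labels, task, spec = NULL, K = 10,
                          seed = 1, averaging = "macro") {
  if (!inherits(task, "TaskSpec")) task <- taskSpec(task)
  if (is.null(spec)) spec <- ensembleSpec(task)
  X <- as.matrix(X)
  m <- mapLabels(as.character(labels), task)
  Xr <- X[m$mask, , drop = FALSE]
  y <- m$labels
  fold <- stratifiedFolds(as.character(y), K, seed = childSeed(seed, 1L))
  perFold <- vector("list", K)
  ensembles <- vector("list", K)
  predLabel <- character(length(y))
  predProb <- numeric(length(y))
  for (k in seq_len(K)) {
    tr <- fold != k
    foldSpec <- ensembleSpec(task, nMembers = spec$nMembers, C = spec$C,
                             gamma = spec$gamma,
                             resampleFraction = spec$resampleFraction,
                             seed = childSeed(seed, 100L + k))
    ens <- trainEnsemble(Xr[tr, , drop = FALSE], y[tr], task, foldSpec)
    ensembles[[k]] <- ens
    pr <- predictEnsemble(ens, Xr[!tr, , drop = FALSE])
    predLabel[!tr] <- as.character(pr$label)
    predProb[!tr] <- pr$meanProbability
    perFold[[k]] <- computeMetrics(
      confusionCounts(y[!tr], pr$label, task$positiveClass), averaging)
  }
  pooledCounts <- confusionCounts(y, predLabel, task$positiveClass)
  out <- list(K = K, task = task, foldAssignment = fold,
              mask = m$mask, perFold = perFold,
              pooled = computeMetrics(pooledCounts, averaging),
              pooledCounts = pooledCounts, ensembles = ensembles,
              predictions = data.frame(
                truth = as.character(y), predicted = predLabel,
                meanProbability = predProb, fold = fold,
                stringsAsFactors = FALSE),
              seed = seed)
  class(out) <- "CVReport"
  out
}

#' @export
print.CVReport <- function(x, ...) {
  cat(sprintf("CVReport: task %s, K = %d\n", x$task$taskId, x$K))
  cat("Pooled: "); print(x$pooled)
  invisible(x)
}

#' Evaluate an ensemble on a prospective set
#'
#' Maps the labels onto the ensemble's task (dropping the absent class
#' for tasks 2-4) and scores the full set.
#'
#' @param ensemble an [SVMEnsemble-class], typically from
#'   [buildOverallEnsemble()].
#' @param X feature matrix aligned with \code{labels}.
#' @param labels three-class labels.
#' @param averaging metric averaging mode.
#' @return a [computeMetrics()] MetricSet with the confusion counts
#'   attached as attribute \code{"counts"}.
#' @export
evaluateProspective <- function(ensemble, X, labels,
                                averaging = "macro") {
  task <- taskSpec(taskId(ensemble))
  X <- as.matrix(X)
  stopIf(length(labels) == 0L || nrow(X) == 0L, "empty prospective set")
  m <- mapLabels(as.character(labels), task)
  stopIf(sum(m$mask) == 0L, "no samples retained for task %s", task$taskId)
  pr <- predictEnsemble(ensemble, X[m$mask, , drop = FALSE])
  counts <- confusionCounts(m$labels, pr$label, task$positiveClass)
  out <- computeMetrics(counts, averaging)
  attr(out, "counts") <- counts
  out
}

#' Chi-square comparison of model and rater accuracies
#'
#' Pearson chi-square on the 2x2 table of correct/incorrect counts for
#' the model versus a (pooled) group of human raters, with optional
#' Yates continuity correction; the p-value comes from the chi-square
#' distribution with 1 degree of freedom.
#'
#' @param modelCorrect,modelTotal model correct answers / total.
#' @param raterCorrect,raterTotal rater correct answers / total
#'   (pooled across the raters in a group).
#' @param continuityCorrection apply the Yates correction.
#' @return list of class \code{"RaterComparison"} with the 2x2 table,
#'   statistic and pValue.
#' @examples
#' compareRaters(74, 90, 382, 450)
#' @export
compareRaters <- function(modelCorrect, modelTotal, raterCorrect,
                          raterTotal, continuityCorrection = FALSE) {
  stopIf(modelTotal <= 0 || raterTotal <= 0, "totals must be positive")
  stopIf(modelCorrect < 0 || modelCorrect > modelTotal,
         "modelCorrect must lie in [0, modelTotal]")
  stopIf(raterCorrect < 0 || raterCorrect > raterTotal,
         "raterCorrect must lie in [0, raterTotal]")
  O <- matrix(c(modelCorrect, modelTotal - modelCorrect,
                raterCorrect, raterTotal - raterCorrect),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("model", "raters"),
                              c("correct", "incorrect")))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  dev <- abs(O - E)
  if (continuityCorrection) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / E)
  structure(list(table = O, statistic = stat,
                 pValue = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 continuityCorrection = continuityCorrection),
            class = "RaterComparison")
}

#' @export
print.RaterComparison <- function(x, ...) {
  cat(sprintf("Chi-square%s: X^2 = %.4f, p = %.4g\n",
              if (x$continuityCorrection) " (Yates)" else "",
              x$statistic, x$pValue))
  print(x$table)
  invisible(x)
}
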