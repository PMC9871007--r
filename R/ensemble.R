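#' Binary task specifications
#'
#' The four binary tasks: (1) normal vs. abnormal (crackles and
#' wheezing pooled as "abnormal"), (2) crackles vs. wheezing, (3)
#' normal vs. crackles, (4) normal vs. wheezing. Tasks 2-4 drop the
#' absent class. Default ensemble sizes are 1, 4, 10 and 4 members
#' respectively.
#'
#' @param task integer 1-4 or a task id string.
#' @return a list of class \code{"TaskSpec"} with taskId, the two
#'   binary class levels (negative, positive) and defaultMembers.
#' @examples
#' taskSpec(3)$defaultMembers  # 10
#' @export
taskSpec <- function(task) {
  if (is.numeric(task)) {
    stopIf(!task %in% 1:4, "task number must be 1-4")
    task <- TASK_IDS[task]
  }
  stopIf(!task %in% TASK_IDS, "unknown task '%s'", task)
  info <- switch(task,
    normal_vs_abnormal   = list(neg = "normal", pos = "abnormal", m = 1L),
    crackles_vs_wheezing = list(neg = "crackles", pos = "wheezing", m = 4L),
    normal_vs_crackles   = list(neg = "normal", pos = "crackles", m = 10L),
    normal_vs_wheezing   = list(neg = "normal", pos = "wheezing", m = 4L))
  structure(list(taskId = task, negativeClass = info$neg,
                 positiveClass = info$pos, defaultMembers = info$m),
            class = "TaskSpec")
}

#' Map three-class labels onto a binary task
#'
#' @param labels character vector over normal/crackles/wheezing.
#' @param task a [taskSpec()] (or its integer/string shorthand).
#' @return list with \code{labels} (factor with levels negative,
#'   positive over the retained rows) and \code{mask} (logical vector of
#'   retained rows; all TRUE for task 1).
#' @export
mapLabels <- function(labels, task) {
  if (!inherits(task, "TaskSpec")) task <- taskSpec(task)
  bad <- setdiff(unique(labels), LUNG_LABELS)
  stopIf(length(bad) > 0, "unknown label(s): %s", paste(bad, collapse = ", "))
  if (task$taskId == "normal_vs_abnormal") {
    mask <- rep(TRUE, length(labels))
    mapped <- ifelse(labels == "normal", "normal", "abnormal")
  } else {
    keep <- c(task$negativeClass, task$positiveClass)
    mask <- labels %in% keep
    mapped <- labels[mask]
  }
  f <- factor(mapped, levels = c(task$negativeClass, task$positiveClass))
  if (length(unique(mapped)) < 2L)
    warning(sprintf("task %s: only one class present after mapping",
                    task$taskId))
  list(labels = f, mask = mask)
}

#' Ensemble specification
#'
#' @param task a [taskSpec()] or shorthand; sets the default member
#'   count (1/4/10/4 for tasks 1-4).
#' @param nMembers number of SVM members in [1, 10]; default per task.
#' @param C RBF-SVM regularization constant.
#' @param gamma kernel width, or "scale" for
#'   \code{1 / (d * var(features))}.
#' @param resampleFraction bootstrap resample size as a fraction of the
#'   training rows (with replacement).
#' @param seed integer seed from which member seeds are derived.
#' @return a list of class \code{"EnsembleSpec"}.
#' @export
ensembleSpec <- function(task, nMembers = NULL, C = 1, gamma = "scale",
                         resampleFraction = 1, seed = 1) {
  if (!inherits(task, "TaskSpec")) task <- taskSpec(task)
  if (is.null(nMembers)) nMembers <- task$defaultMembers
  stopIf(nMembers < 1 || nMembers > 10, "nMembers must lie in [1, 10]")
  stopIf(C <= 0, "C must be positive")
  if (!identical(gamma, "scale"))
    stopIf(!is.numeric(gamma) || gamma <= 0, "gamma must be positive or 'scale'")
  stopIf(resampleFraction <= 0 || resampleFraction > 1,
         "resampleFraction must lie in (0, 1]")
  structure(list(task = task, nMembers = as.integer(nMembers), C = C,
                 gamma = gamma, resampleFraction = resampleFraction,
                 seed = seed),
            class = "EnsembleSpec")
}

resolveGamma <- function(gamma, X) {
  if (identical(gamma, "scale")) {
    v <- stats::var(as.vector(X))
    if (!is.finite(v) || v <= 0) v <- 1
    1 / (ncol(X) * v)
  } else gamma
}

#' Train a single probabilistic RBF-SVM member
#'
#' Fits \code{e1071::svm} (radial kernel, probability output) on a
#' seeded bootstrap resample of the rows. Deterministic given the seed.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y binary factor (both levels present, >= 2 samples each).
#' @param C,gamma,resampleFraction see [ensembleSpec()].
#' @param seed integer seed for the resample and probability
#'   calibration.
#' @return a fitted \code{svm} object.
#' @export
trainMember <- function(X, y, C = 1, gamma = "scale", seed = 1,
                        resampleFraction = 1) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  stopIf(nlevels(y) < 2L, "training data contain a single class")
  stopIf(min(table(y)) < 2L, "need >= 2 samples per class")
  g <- resolveGamma(gamma, X)
  withSeed(seed, {
    n <- nrow(X)
    m <- max(2L, round(n * resampleFraction))
    repeat {  # bootstrap must retain both classes
      idx <- sample(n, m, replace = TRUE)
      if (nlevels(droplevels(y[idx])) == 2L) break
    }
    e1071::svm(x = X[idx, , drop = FALSE], y = y[idx],
               kernel = "radial", cost = C, gamma = g,
               probability = TRUE, scale = TRUE)
  })
}

memberProbabilities <- function(member, X, positiveClass) {
  p <- predict(member, as.matrix(X), probability = TRUE)
  attr(p, "probabilities")[, positiveClass]
}

#' Train a majority-voting SVM ensemble for one binary task
#'
#' Maps the three-class labels onto the task, then trains
#' \code{spec$nMembers} RBF-SVMs on distinct seeded bootstrap
#' resamples.
#'
#' @param X numeric feature matrix aligned with \code{labels}.
#' @param labels three-class labels (normal/crackles/wheezing), or an
#'   already-binary factor matching the task levels.
#' @param task a [taskSpec()] or shorthand.
#' @param spec an [ensembleSpec()]; defaults to the task defaults.
#' @return an [SVMEnsemble-class].
#' @export
trainEnsemble <- function(X, labels, task, spec = NULL) {
  if (!inherits(task, "TaskSpec")) task <- taskSpec(task)
  if (is.null(spec)) spec <- ensembleSpec(task)
  stopIf(!identical(spec$task$taskId, task$taskId),
         "spec was built for task %s", spec$task$taskId)
  X <- as.matrix(X)
  lv <- c(task$negativeClass, task$positiveClass)
  if (all(unique(as.character(labels)) %in% lv)) {
    y <- factor(as.character(labels), levels = lv)
  } else {
    m <- mapLabels(as.character(labels), task)
    X <- X[m$mask, , drop = FALSE]
    y <- m$labels
  }
  seeds <- vapply(seq_len(spec$nMembers),
                  function(k) childSeed(spec$seed, 7000L + k), integer(1))
  members <- lapply(seeds, function(s)
    trainMember(X, y, C = spec$C, gamma = spec$gamma, seed = s,
                resampleFraction = spec$resampleFraction))
  new("SVMEnsemble", members = members, taskId = task$taskId,
      positiveClass = task$positiveClass, classLevels = lv,
      memberSeeds = as.numeric(seeds), featureDim = ncol(X),
      fingerprint = contentFingerprint(dim(X), sum(X), seeds))
}

#' Predict with a majority-voting ensemble
#'
#' Each member votes with its positive-class probability thresholded at
#' 0.5; the majority label wins, and an even split is broken in favor of
#' the class with the higher mean member probability. Member order
#' never affects the outcome.
#'
#' @param ensemble an [SVMEnsemble-class].
#' @param X feature matrix (rows = samples) with \code{featureDim}
#'   columns.
#' @return data.frame with columns \code{label}, \code{meanProbability}
#'   (positive class) and \code{votesPositive}; the full member
#'   probability matrix is attached as attribute
#'   \code{"memberProbabilities"}.
#' @export
predictEnsemble <- function(ensemble, X) {
  X <- as.matrix(X)
  stopIf(ncol(X) != ensemble@featureDim,
         "feature dimension %d does not match training dimension %d",
         ncol(X), ensemble@featureDim)
  P <- vapply(ensemble@members,
              function(m) memberProbabilities(m, X, ensemble@positiveClass),
              numeric(nrow(X)))
  P <- matrix(P, nrow = nrow(X))
  votes <- rowSums(P > 0.5)
  m <- length(ensemble@members)
  meanP <- rowMeans(P)
  lab <- ifelse(votes > m / 2, ensemble@classLevels[2],
         ifelse(votes < m / 2, ensemble@classLevels[1],
                ifelse(meanP >= 0.5, ensemble@classLevels[2],
                       ensemble@classLevels[1])))
  out <- data.frame(label = factor(lab, levels = ensemble@classLevels),
                    meanProbability = meanP, votesPositive = votes)
  attr(out, "memberProbabilities") <- P
  out
}

#' Majority vote on a single feature vector
#'
#' @param ensemble an [SVMEnsemble-class].
#' @param featureVector numeric vector of length \code{featureDim}.
#' @return list with \code{perMemberProbabilities},
#'   \code{majorityLabel} and \code{meanProbability}.
#' @export
vote <- function(ensemble, featureVector) {
  out <- predictEnsemble(ensemble, matrix(featureVector, nrow = 1))
  list(perMemberProbabilities =
         as.numeric(attr(out, "memberProbabilities")[1, ]),
       majorityLabel = as.character(out$label[1]),
       meanProbability = out$meanProbability[1])
}

#' Pool fold ensembles into the overall (nested) ensemble
#'
#' Concatenates the members of every fold's ensemble into one ensemble
#' of K x nMembers members with the same voting rule, as used for
#' prospective validation.
#'
#' @param foldEnsembles list of [SVMEnsemble-class] objects sharing a
#'   task and feature dimension.
#' @return an [SVMEnsemble-class].
#' @export
buildOverallEnsemble <- function(foldEnsembles) {
  stopIf(length(foldEnsembles) < 1, "need at least one fold ensemble")
  tasks <- vapply(foldEnsembles, taskId, character(1))
  stopIf(length(unique(tasks)) != 1L,
         "fold ensembles mix tasks: %s", paste(unique(tasks), collapse = ", "))
  dims <- vapply(foldEnsembles, function(e) e@featureDim, integer(1))
  stopIf(length(unique(dims)) != 1L, "fold ensembles mix feature dimensions")
  e1 <- foldEnsembles[[1]]
  new("SVMEnsemble",
      members = do.call(c, lapply(foldEnsembles, function(e) e@members)),
      taskId = e1@taskId, positiveClass = e1@positiveClass,
      classLevels = e1@classLevels,
      memberSeeds = do.call(c, lapply(foldEnsembles,
                                      function(e) e@memberSeeds)),
      featureDim = e1@featureDim,
      fingerprint = contentFingerprint(
        vapply(foldEnsembles, function(e) e@fingerprint, character(1))))
}
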