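twoBlobs <- function(n = 100, d = 4, sep = 10, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(stats::rnorm(n / 2 * d), ncol = d),
               matrix(stats::rnorm(n / 2 * d, mean = sep), ncol = d))
    colnames(X) <- paste0("f", seq_len(d))
    list(X = X, y = factor(rep(c("normal", "wheezing"), each = n / 2),
                           levels = c("normal", "wheezing")))
  })
}

test_that("task specs and label mapping follow the four binary tasks", {
  expect_equal(taskSpec(1)$taskId, "normal_vs_abnormal")
  expect_equal(vapply(1:4, function(t) taskSpec(t)$defaultMembers,
                      integer(1)), c(1L, 4L, 10L, 4L))
  labs <- c("normal", "crackles", "wheezing")
  m1 <- mapLabels(labs, 1)
  expect_true(all(m1$mask))
  expect_equal(as.character(m1$labels), c("normal", "abnormal", "abnormal"))
  m2 <- mapLabels(labs, 2)
  expect_equal(m2$mask, c(FALSE, TRUE, TRUE))
  expect_equal(as.character(m2$labels), c("crackles", "wheezing"))
  expect_warning(mapLabels(rep("normal", 5), 4), "one class")
  expect_error(mapLabels(c("normal", "murmur"), 1), "murmur")
})

test_that("a single member learns separable data and is reproducible", {
  b <- twoBlobs()
  m <- trainMember(b$X, b$y, seed = 1)
  trainAcc <- mean(predict(m, b$X) == b$y)
  expect_gte(trainAcc, 0.99)
  p1 <- attr(predict(m, b$X, probability = TRUE), "probabilities")
  m2 <- trainMember(b$X, b$y, seed = 1)
  p2 <- attr(predict(m2, b$X, probability = TRUE), "probabilities")
  expect_identical(p1, p2)
  expect_error(trainMember(b$X, factor(rep("a", 100))), "single class")
})

test_that("ensembles have the right size and degenerate correctly", {
  b <- twoBlobs()
  task <- taskSpec(4)
  e1 <- trainEnsemble(b$X, b$y, task, ensembleSpec(task, nMembers = 1,
                                                   seed = 3))
  expect_equal(nMembers(e1), 1)
  pr <- predictEnsemble(e1, b$X)
  memberP <- attr(pr, "memberProbabilities")[, 1]
  expect_equal(as.character(pr$label),
               ifelse(memberP > 0.5, "wheezing", "normal"))
  labs3 <- ifelse(b$y == "normal", "normal", "crackles")
  e10 <- trainEnsemble(b$X, labs3, taskSpec(3), spec = NULL)
  expect_equal(nMembers(e10), 10)  # task-3 default
  expect_equal(length(unique(e10@memberSeeds)), 10)
  # every ensemble size separates the blobs
  for (k in c(2, 5, 10)) {
    ek <- trainEnsemble(b$X, b$y, task, ensembleSpec(task, nMembers = k,
                                                     seed = 3))
    expect_gte(mean(predictEnsemble(ek, b$X)$label == b$y), 0.95)
  }
})

test_that("voting follows majority with mean-probability tie-break", {
  # unanimous members
  e <- stubEnsemble(c(0.9, 0.8, 0.7, 0.6))
  v <- vote(e, 0.5)
  expect_equal(v$majorityLabel, "wheezing")
  expect_equal(v$meanProbability, 0.75)
  expect_equal(v$perMemberProbabilities, c(0.9, 0.8, 0.7, 0.6))
  # 2-2 split, mean positive probability 0.60 -> positive wins
  tie <- stubEnsemble(c(0.9, 0.8, 0.45, 0.25))
  expect_equal(vote(tie, 0)$majorityLabel, "wheezing")
  expect_equal(vote(tie, 0)$meanProbability, 0.6)
  # 2-2 split with mean below 0.5 -> negative wins
  tieNeg <- stubEnsemble(c(0.55, 0.6, 0.1, 0.15))
  expect_equal(vote(tieNeg, 0)$majorityLabel, "normal")
  # permuting member order never changes the outcome
  perm <- stubEnsemble(c(0.45, 0.9, 0.25, 0.8))
  expect_equal(vote(perm, 0)$majorityLabel, vote(tie, 0)$majorityLabel)
  expect_error(predictEnsemble(tie, matrix(0, 1, 3)), "dimension")
})

test_that("overall nested ensemble concatenates fold members", {
  b <- twoBlobs(n = 60)
  task <- taskSpec(4)
  folds <- lapply(1:3, function(k)
    trainEnsemble(b$X, b$y, task, ensembleSpec(task, nMembers = 4,
                                               seed = k)))
  overall <- buildOverallEnsemble(folds)
  expect_equal(nMembers(overall), 12)  # 3 folds x 4 members
  expect_equal(taskId(overall), "normal_vs_wheezing")
  # K = 1 is the identity
  one <- buildOverallEnsemble(folds[1])
  expect_equal(predictEnsemble(one, b$X)$label,
               predictEnsemble(folds[[1]], b$X)$label)
  other <- trainEnsemble(b$X, ifelse(b$y == "normal", "normal", "crackles"),
                         taskSpec(3),
                         ensembleSpec(taskSpec(3), nMembers = 2, seed = 1))
  expect_error(buildOverallEnsemble(list(folds[[1]], other)), "mix tasks")
})

test_that("ensembles persist to disk and restore identically", {
  b <- twoBlobs(n = 40)
  task <- taskSpec(2)
  labs <- ifelse(b$y == "normal", "crackles", "wheezing")
  e <- trainEnsemble(b$X, labs, task, ensembleSpec(task, nMembers = 2,
                                                   seed = 5))
  d <- withr::local_tempdir()
  saveEnsemble(e, d)
  e2 <- loadEnsemble(d)
  expect_equal(nMembers(e2), 2)
  expect_equal(predictEnsemble(e2, b$X), predictEnsemble(e, b$X))
})
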