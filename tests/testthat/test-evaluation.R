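test_that("stratified folds balance classes to within one sample", {
  # 50/50 split, K = 10: every fold exactly 5 + 5
  labs <- rep(c("a", "b"), each = 50)
  f <- stratifiedFolds(labs, 10, seed = 1)
  tab <- table(labs, f)
  expect_true(all(tab == 5))
  # 51/50: fold sizes 10 or 11, class counts within 1 of the share
  labs2 <- c(rep("a", 51), rep("b", 50))
  f2 <- stratifiedFolds(labs2, 10, seed = 2)
  sizes <- table(f2)
  expect_true(all(sizes %in% c(10, 11)))
  tab2 <- table(labs2, f2)
  expect_true(all(abs(tab2["a", ] - 5.1) < 1))
  expect_true(all(abs(tab2["b", ] - 5.0) < 1))
  expect_error(stratifiedFolds(c("a", "a", "b"), 2), "fewer than")
  expect_identical(f, stratifiedFolds(labs, 10, seed = 1))
})

test_that("fold assignment is a partition with bounded deviation", {
  withr::with_seed(99, {
    for (rep in 1:100) {
      n <- sample(30:120, 1)
      K <- sample(2:5, 1)
      labs <- sample(c("normal", "crackles", "wheezing"), n,
                     replace = TRUE,
                     prob = stats::runif(3, 0.2, 1))
      counts <- table(labs)
      if (any(counts < K)) next
      f <- stratifiedFolds(labs, K, seed = rep)
      expect_length(f, n)
      expect_true(all(f %in% seq_len(K)))
      tab <- table(factor(labs), factor(f, levels = seq_len(K)))
      share <- matrix(counts / K, nrow(tab), K)
      expect_true(all(abs(tab - share) < 1))
    }
  })
})

test_that("metric formulas match hand-computed confusion values", {
  cc <- confusionCounts(c("p", "p", "p", "p", "n", "n", "n", "n", "n", "n"),
                        c("p", "p", "p", "n", "p", "n", "n", "n", "n", "n"),
                        positive = "p")
  expect_equal(cc$TP, 3); expect_equal(cc$FP, 1)
  expect_equal(cc$FN, 1); expect_equal(cc$TN, 5)
  m <- computeMetrics(cc, "positive_class")
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  # perfect predictions
  perfect <- structure(list(TP = 4, FP = 0, FN = 0, TN = 6),
                       class = "ConfusionCounts")
  mp <- computeMetrics(perfect, "macro")
  expect_equal(unlist(mp[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # zero-denominator convention: reported as 0 and flagged
  zd <- structure(list(TP = 0, FP = 0, FN = 2, TN = 8),
                  class = "ConfusionCounts")
  mz <- computeMetrics(zd, "positive_class")
  expect_equal(mz$precision, 0)
  expect_equal(mz$accuracy, 0.8)
  expect_true("precision" %in% attr(mz, "undefined"))
  # scale-free: multiplying all counts by 10 changes nothing
  big <- structure(lapply(cc, `*`, 10), class = "ConfusionCounts")
  expect_equal(unclass(computeMetrics(big, "macro")),
               unclass(computeMetrics(cc, "macro")))
})

test_that("cross-validation scores each sample once and pools folds", {
  withr::with_seed(31, {
    X <- cbind(stats::runif(120), stats::rnorm(120))
    labs <- rep(c("normal", "wheezing"), each = 60)
    X[labs == "wheezing", 1] <- X[labs == "wheezing", 1] + 3
  })
  cv <- crossValidate(X, labs, 4, K = 5, seed = 2)
  expect_length(cv$perFold, 5)
  expect_equal(sort(unique(cv$foldAssignment)), 1:5)
  expect_equal(nrow(cv$predictions), 120)
  # pooled confusion counts equal the sum over folds
  byFold <- split(cv$predictions, cv$predictions$fold)
  total <- Reduce(`+`, lapply(byFold, function(d)
    unlist(confusionCounts(d$truth, d$predicted, "wheezing"))))
  expect_equal(unlist(cv$pooledCounts), total)
  # determinism
  cv2 <- crossValidate(X, labs, 4, K = 5, seed = 2)
  expect_identical(cv$foldAssignment, cv2$foldAssignment)
  expect_equal(cv$pooled, cv2$pooled)
})

test_that("a constant majority-class stub scores the majority share", {
  # members that always emit probability 0.1 predict 'normal' for every
  # sample, so pooled accuracy must equal the normal-class proportion
  e <- stubEnsemble(c(0.1, 0.1, 0.1))
  X <- matrix(0.5, 40, 1)
  labs <- c(rep("normal", 25), rep("wheezing", 15))
  met <- evaluateProspective(e, X, labs, averaging = "positive_class")
  expect_equal(met$accuracy, 25 / 40)
  # a memorizing stub (probability = truth indicator) is perfect
  mem <- stubEnsemble(NA)
  Xm <- matrix(as.numeric(labs == "wheezing"), ncol = 1)
  expect_equal(evaluateProspective(mem, Xm, labs)$accuracy, 1)
  expect_error(evaluateProspective(e, X[0, , drop = FALSE],
                                   character(0)), "empty")
})

test_that("chi-square comparison matches the Pearson formula", {
  # identical proportions: no association
  same <- compareRaters(40, 50, 80, 100)
  expect_equal(same$statistic, 0)
  expect_equal(same$pValue, 1)
  # hand-computed Pearson sum((O-E)^2/E) oracle
  O <- matrix(c(74, 16, 382, 68), 2, 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  statHand <- sum((O - E)^2 / E)
  got <- compareRaters(74, 90, 382, 450)
  expect_equal(got$statistic, statHand, tolerance = 1e-12)
  expect_equal(got$pValue, stats::pchisq(statHand, 1, lower.tail = FALSE))
  # independent cross-check against the standard implementation
  ref <- suppressWarnings(stats::chisq.test(O, correct = FALSE))
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$pValue, unname(ref$p.value), tolerance = 1e-12)
  refY <- suppressWarnings(stats::chisq.test(O, correct = TRUE))
  gotY <- compareRaters(74, 90, 382, 450, continuityCorrection = TRUE)
  expect_equal(gotY$statistic, unname(refY$statistic), tolerance = 1e-12)
  # Yates statistic never exceeds the uncorrected one
  withr::with_seed(5, {
    for (i in 1:25) {
      mt <- sample(20:200, 1); rt <- sample(20:200, 1)
      mc <- sample(0:mt, 1); rc <- sample(0:rt, 1)
      expect_lte(compareRaters(mc, mt, rc, rt, TRUE)$statistic,
                 compareRaters(mc, mt, rc, rt, FALSE)$statistic + 1e-12)
    }
  })
  expect_error(compareRaters(5, 0, 1, 10), "positive")
})
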