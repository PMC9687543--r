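test_that("k-fold pair splits partition the positives without leakage", {
  set.seed(1)
  A <- matrix(0, 8, 10); A[sample(80, 20)] <- 1
  sp <- kfoldPairSplit(A, 10, seed = 3)
  expect_length(sp, 10)
  sizes <- vapply(sp, function(s) nrow(s$testPositive), integer(1))
  expect_true(all(sizes == 2))
  # union of test folds = all positives, pairwise disjoint
  key <- function(m) paste(m[, 1], m[, 2])
  allTest <- unlist(lapply(sp, function(s) key(s$testPositive)))
  expect_setequal(allTest, key(which(A == 1, arr.ind = TRUE)))
  expect_equal(anyDuplicated(allTest), 0)
  for (s in sp) {
    td <- splitTrainingData(s, A)
    expect_true(all(td$trainA[s$testPositive] == 0))
    expect_true(all(td$lossMask[s$testPositive] == 0))
  }
  # same seed, same split
  expect_identical(sp, kfoldPairSplit(A, 10, seed = 3))
  expect_error(kfoldPairSplit(A, 25, seed = 1), "fewer positives")

  # negative subsampling bounds the training negatives
  spN <- kfoldPairSplit(A, 4, seed = 2, negRatio = 2)
  for (s in spN) {
    expect_equal(nrow(s$trainNegative), 2 * nrow(s$trainPositive))
    td <- splitTrainingData(s, A)
    expect_equal(sum(td$lossMask * (A == 0)), nrow(s$trainNegative))
  }
  # positive subsampling removes pairs from the experiment
  spP <- kfoldPairSplit(A, 4, seed = 2, positiveFraction = 0.8)
  expect_equal(nrow(spP[[1]]$droppedPositive), 4)
})

test_that("cold-start splits hold out whole disease columns", {
  set.seed(2)
  A <- matrix(rbinom(40 * 25, 1, 0.15), 25, 40)
  sp <- novelDiseaseSplit(A, 0.2, seed = 5)
  expect_length(sp$heldDiseases, 8)
  td <- splitTrainingData(sp, A)
  colSumsTrain <- colSums(td$trainA)
  expect_true(all(colSumsTrain[sp$heldDiseases] == 0))
  expect_true(all(colSumsTrain[-sp$heldDiseases] == colSums(A)[-sp$heldDiseases]))
  # evaluation universe is the held-out columns
  ev <- evaluationPairs(sp, A)
  expect_setequal(unique(ev$pairs[, 2]), sp$heldDiseases)
  expect_equal(sum(ev$labels), sum(A[, sp$heldDiseases]))

  # partition mode covers every disease exactly once over the cycle
  held <- unlist(lapply(1:5, function(r)
    novelDiseaseSplit(A, 0.2, seed = r, mode = "partition")$heldDiseases))
  expect_setequal(held, 1:40)
  expect_equal(anyDuplicated(held), 0)
})

test_that("ranking metrics match brute-force pair counting and closed forms", {
  # 4-point hand example: exhaustive positive-negative pair comparison
  sc <- c(0.9, 0.8, 0.3, 0.1); lb <- c(1, 0, 1, 0)
  m <- computeMetrics(sc, lb)
  expect_equal(m$auroc, 0.75)

  # brute-force oracle on random instances
  set.seed(6)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    sc <- round(runif(n), 2)          # force ties
    lb <- rbinom(n, 1, 0.4)
    if (sum(lb) == 0) lb[1] <- 1
    if (sum(lb) == n) lb[n] <- 0
    pos <- sc[lb == 1]; neg <- sc[lb == 0]
    brute <- mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
    expect_equal(computeMetrics(sc, lb)$auroc, brute, tolerance = 1e-12)
  }

  # perfect separation and anti-separation
  expect_equal(computeMetrics(c(.9, .8, .2, .1), c(1, 1, 0, 0))$auroc, 1)
  expect_equal(computeMetrics(c(.9, .8, .2, .1), c(1, 1, 0, 0))$aupr, 1)
  expect_equal(computeMetrics(c(.1, .2, .8, .9), c(1, 1, 0, 0))$auroc, 0)

  # random scores: AUROC near 1/2 within 3 sd of the rank statistic
  set.seed(7)
  n <- 4000; lb <- rbinom(n, 1, 0.3); sc <- runif(n)
  np <- sum(lb); nn <- n - np
  sdU <- sqrt((np + nn + 1) / (12 * np * nn))
  expect_lt(abs(computeMetrics(sc, lb)$auroc - 0.5), 3 * sdU)

  # threshold metrics at 0.5
  m2 <- computeMetrics(c(0.9, 0.6, 0.4, 0.2), c(1, 0, 1, 0), threshold = 0.5)
  expect_equal(m2$recall, 0.5)
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$f1, 0.5)
  expect_error(computeMetrics(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  sc <- runif(300); lb <- rbinom(300, 1, 0.25)
  ours <- computeMetrics(sc, lb)$auroc
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("top-k recovery equals a sort-and-count oracle", {
  set.seed(9)
  sc <- runif(50); lb <- rbinom(50, 1, 0.3)
  for (k in c(1, 5, 20, 50)) {
    ord <- order(-sc, seq_along(sc))
    expect_equal(topkRecovery(sc, lb, k), sum(lb[ord[1:k]]))
  }
  # separable scores recover all positives at k = |positives|
  scS <- c(rep(0.9, 4), rep(0.1, 6)); lbS <- c(rep(1, 4), rep(0, 6))
  expect_equal(topkRecovery(scS, lbS, 4), 4)
  expect_error(topkRecovery(sc, lb, 0), "positive")
  expect_error(topkRecovery(sc, lb, 51), "exceeds")
})

test_that("cross-validation trains per fold, aggregates means, and never leaks", {
  ds <- generateDataset(synthConfig(M = 12, N = 14, P = 15, S = 2, rank = 2,
                                    density = 0.25, seed = 13))
  cfg <- modelConfig(k1 = 8, k2 = 6, K = 3, epochs = 30, lr = 0.01,
                     beta = 0.2, gamma = 0.1, seed = 31)
  rep2 <- crossValidate(ds$network, cfg, "kfold", folds = 2, seed = 2)
  expect_equal(nrow(rep2$perFold), 2)
  expect_equal(unname(rep2$mean["auroc"]), mean(rep2$perFold$auroc))
  expect_true(all(rep2$perFold$auroc >= 0 & rep2$perFold$auroc <= 1))

  repN <- crossValidate(ds$network, cfg, "novel", repeats = 2, fraction = 0.2,
                        seed = 4)
  expect_equal(nrow(repN$perFold), 2)

  # determinism of the whole protocol
  rep2b <- crossValidate(ds$network, cfg, "kfold", folds = 2, seed = 2)
  expect_identical(rep2$perFold, rep2b$perFold)
})
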