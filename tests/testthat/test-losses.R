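# Loss and metric formulas against hand computations and brute-force
# oracles.

test_that("dice loss: perfect overlap, disjoint masks, hand-computed value", {
  set.seed(1)
  Y <- matrix(rbinom(64, 1, 0.4), 8)
  expect_lt(diceLoss(Y, Y), 1e-5)
  expect_gt(diceLoss(matrix(1, 8, 8), matrix(0, 8, 8)), 1 - 1e-4)
  # |X ∩ Y| = 2, |X| = |Y| = 3 -> 1 - 4/6
  X <- matrix(0, 4, 4); X[c(1, 2, 3)] <- 1
  Y2 <- matrix(0, 4, 4); Y2[c(2, 3, 8)] <- 1
  expect_equal(diceLoss(X, Y2), 1 - 4 / 6, tolerance = 1e-6)
  expect_error(diceLoss(matrix(0, 4, 4), matrix(0, 5, 5)), "shape")
})

test_that("BCE loss: closed form at 0.5, near-zero at perfect, monotone in X", {
  set.seed(2)
  Y <- matrix(rbinom(100, 1, 0.5), 10)
  expect_equal(bceLoss(matrix(0.5, 10, 10), Y), log(2), tolerance = 1e-12)
  expect_lt(bceLoss(Y, Y), 1e-5)
  # strictly decreasing in X_p where Y_p = 1
  X <- matrix(0.5, 10, 10)
  X2 <- X
  pos <- which(Y == 1)[1]
  X2[pos] <- 0.6
  expect_lt(bceLoss(X2, Y), bceLoss(X, Y))
})

test_that("joint loss is the exact unweighted sum and bounds its parts", {
  set.seed(3)
  X <- matrix(runif(64), 8)
  Y <- matrix(rbinom(64, 1, 0.3), 8)
  expect_equal(jointLoss(X, Y), diceLoss(X, Y) + bceLoss(X, Y))
  expect_gte(jointLoss(X, Y), max(diceLoss(X, Y), bceLoss(X, Y)))
  # worked arithmetic: components (1/3, ln 2)
  expect_equal(1 - 4 / 6 + log(2), 1.0265, tolerance = 1e-4)
})

test_that("confusion counts match the double-loop oracle exactly on 200 pairs", {
  set.seed(4)
  for (trial in 1:200) {
    pred <- matrix(rbinom(256, 1, runif(1, 0.1, 0.9)), 16)
    gt <- matrix(rbinom(256, 1, runif(1, 0.1, 0.9)), 16)
    expect_identical(confusionCounts(pred, gt)[1:3],
                     naiveConfusion(pred, gt)[1:3])
    m <- segmentationMetrics(pred, gt)
    cc <- naiveConfusion(pred, gt)
    if (2 * cc[["TP"]] + cc[["FP"]] + cc[["FN"]] > 0) {
      expect_equal(m[["DSC"]],
                   200 * cc[["TP"]] / (cc[["FP"]] + 2 * cc[["TP"]] + cc[["FN"]]))
      expect_equal(m[["JSC"]],
                   100 * cc[["TP"]] / (cc[["FP"]] + cc[["TP"]] + cc[["FN"]]))
    }
  }
})

test_that("the 2x2 worked example and degenerate conventions hold", {
  pred <- matrix(c(1, 1, 1, 0), 2, byrow = TRUE)
  gt <- matrix(c(1, 0, 1, 1), 2, byrow = TRUE)
  cc <- confusionCounts(pred, gt)
  expect_identical(cc, c(TP = 2L, FP = 1L, FN = 1L, TN = 0L))
  m <- segmentationMetrics(pred, gt)
  expect_equal(m[["DSC"]], 66.67, tolerance = 1e-3)
  expect_equal(m[["SEN"]], 66.67, tolerance = 1e-3)
  expect_equal(m[["JSC"]], 50)
  # complementary masks: TP = TN = 0
  cinv <- confusionCounts(1 - gt, gt)
  expect_identical(cinv[["TP"]] + cinv[["TN"]], 0L)
  # both empty -> vacuous perfection; prediction on empty gt -> 0
  e <- matrix(0, 3, 3)
  expect_equal(unname(segmentationMetrics(e, e)), c(100, 100, 100))
  expect_equal(segmentationMetrics(matrix(1, 3, 3), e)[["SEN"]], 0)
  expect_equal(unname(segmentationMetrics(e, matrix(1, 3, 3))),
               c(0, 0, 0))
})

test_that("JSC = DSC / (2 - DSC) and dice loss complements DSC on binary input", {
  set.seed(5)
  for (trial in 1:50) {
    pred <- matrix(rbinom(144, 1, 0.5), 12)
    gt <- matrix(rbinom(144, 1, 0.5), 12)
    m <- segmentationMetrics(pred, gt)
    if (sum(pred) + sum(gt) > 0) {
      d <- m[["DSC"]] / 100
      expect_equal(m[["JSC"]] / 100, d / (2 - d), tolerance = 1e-10)
      expect_equal(diceLoss(pred, gt), 1 - d, tolerance = 1e-5)
    }
  }
})

test_that("metric thresholding binarizes probabilities as documented", {
  gt <- matrix(1, 2, 2)
  expect_equal(segmentationMetrics(matrix(0.6, 2, 2), gt)[["DSC"]], 100)
  expect_equal(segmentationMetrics(matrix(0.6, 2, 2),
                                   matrix(0, 2, 2))[["DSC"]], 0)
  expect_error(segmentationMetrics(matrix(0.6, 2, 2), gt, threshold = 0),
               "threshold")
})

test_that("paired t-test matches a closed-form oracle and handles degeneracies", {
  expect_identical(pairedTTest(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(pairedTTest(c(1, 2, 3, 4), c(2, 3, 4, 5)),
               .Machine$double.xmin)
  a <- c(1.0, 2.0, 3.0, 4.0)
  b <- c(1.1, 2.3, 2.7, 4.4)
  expect_equal(pairedTTest(a, b), naivePairedT(a, b), tolerance = 1e-12)
  set.seed(6)
  for (trial in 1:20) {
    a <- rnorm(5); b <- rnorm(5)
    expect_equal(pairedTTest(a, b), naivePairedT(a, b), tolerance = 1e-10)
  }
  expect_error(pairedTTest(1:3, 1:4), "equal-length")
  expect_error(pairedTTest(1, 2), "n >= 2")
})
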