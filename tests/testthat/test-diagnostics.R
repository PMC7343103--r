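test_that("confusion matrix tabulates predictions against truth", {
  # all correct
  r <- makeResults(c(-1, -1, 1, 1), c("cancer", "cancer", "control", "control"))
  cm <- confusionMatrix(r)
  expect_identical(c(cm@tp, cm@fn, cm@tn, cm@fp), c(2L, 0L, 2L, 0L))
  # empty input: all-zero matrix
  cm0 <- confusionMatrix(makeResults(numeric(0), character(0)))
  expect_identical(c(cm0@tp, cm0@fn, cm0@tn, cm0@fp), rep(0L, 4))
  # excluded samples never enter the matrix
  r2 <- makeResults(c(-1, 5, -1), c("cancer", "cancer", "control"),
                    excluded = c(FALSE, TRUE, FALSE))
  cm2 <- confusionMatrix(r2)
  expect_identical(c(cm2@tp, cm2@fn, cm2@tn, cm2@fp), c(1L, 0L, 0L, 1L))
  # missing truth is an error
  r3 <- makeResults(c(-1, 1), c("cancer", NA))
  expect_error(confusionMatrix(r3), "arm")
})

test_that("sensitivity and specificity follow their definitions", {
  cm <- ConfusionMatrix(tp = 6, fn = 2, tn = 7, fp = 1)
  expect_equal(sensitivity(cm), 0.75)
  expect_equal(specificity(cm), 0.875)
  expect_equal(sensitivity(ConfusionMatrix(tp = 0, fn = 5, tn = 1, fp = 1)), 0)
  expect_equal(sensitivity(ConfusionMatrix(tp = 6, fn = 0, tn = 1, fp = 1)), 1)
  expect_equal(specificity(ConfusionMatrix(tp = 1, fn = 1, tn = 6, fp = 1)),
               6 / 7, tolerance = 1e-12)
  expect_equal(specificity(ConfusionMatrix(tp = 1, fn = 1, tn = 0, fp = 3)), 0)
  expect_error(sensitivity(ConfusionMatrix(tp = 0, fn = 0, tn = 5, fp = 1)),
               "no positive")
  expect_error(specificity(ConfusionMatrix(tp = 3, fn = 1, tn = 0, fp = 0)),
               "no negative")
  # label-swap symmetry: swapping tp<->tn and fn<->fp swaps the two rates
  cmSwap <- ConfusionMatrix(tp = 7, fn = 1, tn = 6, fp = 2)
  expect_equal(sensitivity(cmSwap), specificity(cm))
  expect_equal(specificity(cmSwap), sensitivity(cm))
})

test_that("two-sample t-test matches the textbook pooled formula", {
  a <- c(0.12, -0.34, 0.05, 0.41, -0.20)
  b <- c(0.55, 0.61, 0.38, 0.72, 0.49)
  ours <- mdvTTest(a, b, "pooled")
  oracle <- oraclePooledT(a, b)
  expect_equal(ours$statistic, unname(oracle["t"]), tolerance = 1e-12)
  expect_equal(ours$pValue, unname(oracle["p"]), tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  same <- mdvTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$pValue, 1)
  # large separation: p -> 0
  far <- mdvTTest(c(1, 2, 3), c(1, 2, 3) + 1e3)
  expect_lt(far$pValue, 1e-10)
  # degenerate zero-variance case by convention
  expect_equal(mdvTTest(c(2, 2), c(2, 2))$pValue, 1)
  expect_equal(mdvTTest(c(2, 2), c(3, 3))$pValue, 0)
  expect_error(mdvTTest(1, c(1, 2)), "at least 2")
  # Welch coincides with pooled for equal sizes and equal variances
  x <- c(1, 2, 3, 4); y <- c(11, 12, 13, 14)
  expect_equal(mdvTTest(x, y, "pooled")$pValue,
               mdvTTest(x, y, "welch")$pValue, tolerance = 1e-10)
})

test_that("threshold sweep finds the brute-force Youden optimum", {
  # perfectly separated: some threshold reaches Youden 1
  sep <- makeResults(c(-2, -1.5, -1.2, 0.5, 0.8, 1.1),
                     rep(c("cancer", "control"), each = 3))
  opt <- thresholdSweep(sep)$optimum
  expect_equal(opt$youden, 1)
  expect_equal(opt$sensitivity, 1)
  expect_equal(opt$specificity, 1)
  expect_gt(opt$threshold, -1.2); expect_lt(opt$threshold, 0.5)
  expect_equal(opt$interval, c(-1.2, 0.5))
  # property: optimum equals brute-force maximisation on random sets
  set.seed(17)
  for (i in 1:40) {
    n <- sample(4:20, 1)
    arm <- sample(c("cancer", "control"), n, replace = TRUE)
    if (length(unique(arm)) < 2) arm[1:2] <- c("cancer", "control")
    mdv <- round(rnorm(n), 2)  # rounding forces occasional ties
    r <- makeResults(mdv, arm)
    sw <- thresholdSweep(r)
    expect_equal(sw$optimum$youden, oracleYoudenOptimum(mdv, arm))
    # the reported optimum threshold attains the optimal Youden index
    pred <- classifyMDV(mdv, sw$optimum$threshold)
    se <- sum(pred == "cancer" & arm == "cancer") / sum(arm == "cancer")
    sp <- sum(pred == "control" & arm == "control") / sum(arm == "control")
    expect_equal(se + sp - 1, sw$optimum$youden)
  }
  # one-arm input hits the documented error path
  expect_error(thresholdSweep(makeResults(c(-1, 0), c("cancer", "cancer"))),
               "both arms")
})

test_that("the full pipeline reports pre- and post-exclusion performance", {
  # zero noise, no artefacts: both passes identical and perfect after
  # sweep calibration
  clean <- cohortConfig(noiseSD = 0, deadWells = 0, lowCellCancer = 0,
                        seed = 31)
  ansClean <- runFullAnalysis(simulateCohort(clean), thresholdMode = "sweep")
  expect_identical(ansClean$unfiltered@confusion, ansClean$filtered@confusion)
  expect_equal(ansClean$unfiltered@sensitivity, 1)
  expect_equal(ansClean$unfiltered@specificity, 1)
  expect_identical(ansClean$filtered@nExcluded, 0L)
  # default conditions: three injected low-cell cancer samples excluded,
  # sensitivity recovers to 1 after exclusion
  ans <- runFullAnalysis(simulateCohort(cohortConfig(seed = 8)),
                         thresholdMode = "sweep")
  expect_identical(ans$filtered@nExcluded, 3L)
  expect_gte(ans$filtered@sensitivity, ans$unfiltered@sensitivity)
  # exclusion never changes a retained sample's MDV
  keep <- !ans$mdv$excluded
  proc <- maskDeadPoints(medianAcrossRepeats(
    simulateCohort(cohortConfig(seed = 8))))
  expect_equal(ans$mdv$mdv[keep],
               computeMDV(proc)$mdv[keep])
  # determinism of the analysis given the cohort
  ans2 <- runFullAnalysis(simulateCohort(cohortConfig(seed = 8)),
                          thresholdMode = "sweep")
  expect_identical(ans$mdv, ans2$mdv)
  expect_identical(ans$filtered@pValue, ans2$filtered@pValue)
})
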