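freqs4 <- c(1e4, 1e5, 1e6, 1e7)

test_that("per-sample medians follow the midpoint rule", {
  m <- cbind(c(1, 0, 5, 7), c(2, 1, 5, 7), c(10, 3, 5, 7))
  cohort <- makeDepCohort(list(A = m), freqs4, "cancer")
  proc <- medianAcrossRepeats(cohort)
  expect_equal(unname(medianSpectra(proc)[, 1]), c(2, 1, 5, 7))
  expect_identical(colData(proc)$n_repeats_used, 3L)
  # even count: midpoint of the two central values
  m4 <- cbind(c(0, 0, 0, 0), c(1, 1, 1, 1), c(3, 3, 3, 3), c(100, 100, 100, 100))
  proc4 <- medianAcrossRepeats(makeDepCohort(list(B = m4), freqs4, "control"))
  expect_equal(unname(medianSpectra(proc4)[, 1]), rep(2, 4))
  # single repeat: identity
  one <- matrix(c(1, -2, 3, 4), ncol = 1)
  procOne <- medianAcrossRepeats(makeDepCohort(list(C = one), freqs4, "cancer"))
  expect_equal(unname(medianSpectra(procOne)[, 1]), c(1, -2, 3, 4))
  # median commutes with repeat reordering
  perm <- m[, c(3, 1, 2)]
  procP <- medianAcrossRepeats(makeDepCohort(list(A = perm), freqs4, "cancer"))
  expect_identical(medianSpectra(procP), medianSpectra(proc))
})

test_that("dead-point detection flags near-zero outliers only", {
  curve <- c(-0.8, -0.4, 0.001, 0.5, 0.8, 0.7, 0.6, 0.4)
  expect_identical(which(detectDeadPoints(curve, 0.05)), 3L)
  # a uniformly near-zero (low-cell) spectrum is left alone
  expect_identical(sum(detectDeadPoints(rnorm(20, 0, 0.01), 0.05)), 0L)
  # masking never alters stored values
  proc <- makeProcessed(matrix(curve, ncol = 1), seq_along(curve) * 1e4,
                        "cancer")
  masked <- maskDeadPoints(proc, 0.05)
  expect_identical(medianSpectra(masked), medianSpectra(proc))
  expect_identical(unname(which(!validMask(masked)[, 1])), 3L)
})

test_that("injected dead points are recovered across simulated cohorts", {
  detected <- 0L; injected <- 0L; falseMasks <- 0L; clearPoints <- 0L
  med <- defaultMedium()
  for (s in 1:100) {
    cfg <- cohortConfig(deadWells = 0, deadPointProb = 0.05,
                        lowCellCancer = 0, seed = 5000 + s)
    cohort <- simulateCohort(cfg)
    # no per-sample cap here: this measures the detection rule itself
    proc <- maskDeadPoints(medianAcrossRepeats(cohort), 0.05, maxMasked = 20L)
    mask <- validMask(proc)
    truthDead <- S4Vectors::metadata(cohort)$deadPoints
    cells <- S4Vectors::metadata(cohort)$cellParams
    for (id in sampleIds(cohort)) {
      dead <- truthDead[[id]]
      injected <- injected + length(dead)
      detected <- detected + sum(!mask[dead, id])
      # false-mask rate judged on points whose true signal is clearly
      # away from zero; near-crossover points are indeterminate by any
      # magnitude rule
      trueVal <- depSpectrum(cells[[id]], med, cfg$frequencies,
                             gain = cfg$gain)
      clear <- setdiff(which(abs(trueVal) > 0.1), dead)
      clearPoints <- clearPoints + length(clear)
      falseMasks <- falseMasks + sum(!mask[clear, id])
    }
  }
  expect_gt(injected, 1000L)
  expect_gte(detected / injected, 0.95)
  expect_lte(falseMasks / clearPoints, 0.01)
})

test_that("rolling average matches hand computations", {
  expect_equal(rollingAverage(c(1, 3), 2), 2)
  expect_equal(rollingAverage(c(1, 2, 4, 8), 2), c(1.5, 3, 6))
  expect_equal(rollingAverage(rep(5, 7), 3), rep(5, 5))
  expect_identical(rollingAverage(c(3, 1, 4), 1), c(3, 1, 4))
  # masked points are dropped before windowing
  expect_equal(rollingAverage(c(1, 99, 3), 2, mask = c(TRUE, FALSE, TRUE)), 2)
  expect_error(rollingAverage(c(1, 2), 3), "window")
})

test_that("arm means omit masked points per frequency", {
  med <- cbind(A = c(1, 2, 3, 4), B = c(3, 4, 5, 6), C = c(5, 6, 9, 8))
  mask <- matrix(TRUE, 4, 3); mask[3, 3] <- FALSE
  proc <- makeProcessed(med, freqs4, rep("cancer", 3), mask)
  am <- armMeanSpectrum(proc, "cancer")
  expect_equal(am$mean, c(3, 4, 4, 6))
  expect_equal(am$n, c(3, 3, 2, 3))
  # single sample: identity
  solo <- makeProcessed(cbind(A = c(1, -1, 2, 0)), freqs4, "control")
  expect_equal(armMeanSpectrum(solo, "control")$mean, c(1, -1, 2, 0))
  # symmetric samples cancel
  pair <- makeProcessed(cbind(A = c(1, 2, -3, 4), B = -c(1, 2, -3, 4)),
                        freqs4, rep("control", 2))
  expect_equal(armMeanSpectrum(pair, "control")$mean, rep(0, 4))
  # linearity in the input values
  twice <- makeProcessed(2 * med, freqs4, rep("cancer", 3), mask)
  expect_equal(armMeanSpectrum(twice, "cancer")$mean, 2 * am$mean)
  # all samples masked at one frequency: NA there
  maskAll <- matrix(TRUE, 4, 3); maskAll[2, ] <- FALSE
  procAll <- makeProcessed(med, freqs4, rep("cancer", 3), maskAll)
  expect_true(is.na(armMeanSpectrum(procAll, "cancer")$mean[2]))
  expect_error(armMeanSpectrum(proc, "control"), "no samples")
})
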