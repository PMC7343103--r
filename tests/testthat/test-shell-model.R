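test_that("complex permittivity follows the standard dispersion", {
  # zero conductivity: purely real
  expect_equal(complexPermittivity(78, 0, 1e5), 78 + 0i)
  # high-frequency limit: loss term vanishes
  expect_lt(abs(Im(complexPermittivity(78, 0.043, 1e15))), 1e-6)
  # direct arithmetic oracle at 100 kHz
  expect_equal(complexPermittivity(78, 0.043, 1e5),
               oracleComplexPerm(78, 0.043, 1e5), tolerance = 1e-12)
  expect_lte(Im(complexPermittivity(78, 0.043, 1e4)), 0)
  expect_error(complexPermittivity(78, 0.043, 0), "positive")
  expect_error(complexPermittivity(78, 0.043, -5), "positive")
})

test_that("single-shell effective permittivity has the right limits", {
  f <- defaultGrid()
  # vanishing shell contrast: membrane built from cytoplasm material with
  # tiny thickness collapses onto the cytoplasm permittivity
  d <- 1e-12
  cell <- ShellParams(10e-6, 8.854e-12 * 60 / d, 0.25 / d, 60, 0.25)
  expect_equal(singleShellPermittivity(cell, f),
               complexPermittivity(60, 0.25, f), tolerance = 1e-4)
  # DC limit with insulating membrane: effective conductivity -> 0
  cellIns <- ShellParams(10e-6, 0.01, 0, 60, 0.25)
  effLow <- singleShellPermittivity(cellIns, 1e-2)
  sigEff <- -Im(effLow) * 2 * pi * 1e-2 * 8.854e-12
  expect_lt(abs(sigEff), 1e-12)
  expect_error(ShellParams(-1e-6, 0.01, 0, 60, 0.25), "radius")
})

test_that("thin-shell model matches a finite-thickness two-layer oracle", {
  f <- defaultGrid()
  cases <- list(c(10e-6, 0.01, 2000, 60, 0.25),
                c(10e-6, 0.01, 200, 60, 0.5),
                c(5e-6, 0.02, 500, 50, 0.8))
  for (p in cases) {
    thin <- singleShellPermittivity(do.call(ShellParams, as.list(p)), f)
    for (d in c(5e-9, 10e-9)) {
      fat <- oracleFiniteShellPerm(p[1], p[2], p[3], p[4], p[5], f, d)
      expect_lt(max(abs(thin - fat) / abs(fat)), 0.01)
    }
  }
})

test_that("Re[CM] is bounded, continuous and matches closed-form limits", {
  med <- refMedium()
  # zero dielectric contrast: shell collapsed onto medium material
  d <- 1e-12
  same <- ShellParams(10e-6, 8.854e-12 * 78 / d, 0.043 / d, 78, 0.043)
  expect_lt(max(abs(reCM(same, med, defaultGrid()))), 1e-4)
  # insulating sphere DC limit in a conductive medium
  ins <- ShellParams(10e-6, 0.01, 0, 60, 0.25)
  expect_equal(reCM(ins, med, 1e-1), -0.5, tolerance = 1e-6)
  # high-frequency limit from the permittivity contrast alone (a large
  # whole-cell capacitance r*C_mem makes the membrane transparent there)
  insHiC <- ShellParams(10e-6, 0.1, 0, 60, 0.25)
  expect_equal(reCM(insHiC, med, 1e13), (60 - 78) / (60 + 2 * 78),
               tolerance = 0.01)
  # bounds and finiteness over random parameter draws
  set.seed(42)
  f <- defaultGrid(50)
  for (i in 1:50) {
    cell <- ShellParams(runif(1, 2e-6, 20e-6), runif(1, 0.002, 0.05),
                        runif(1, 0, 5000), runif(1, 40, 90),
                        runif(1, 0.05, 1.5))
    m <- DielectricMedium(runif(1, 40, 90), runif(1, 0.001, 0.2))
    v <- reCM(cell, m, f)
    expect_true(all(is.finite(v)))
    expect_true(all(v >= -0.5 - 1e-9 & v <= 1 + 1e-9))
    expect_lt(max(abs(diff(v))), 0.6)  # no jumps on a fine log grid
  }
})

test_that("model spectra compose pointwise and show the two-state contrast", {
  med <- refMedium()
  arms <- defaultArms()
  f <- defaultGrid()
  ctrl <- depSpectrum(arms$control@centre, med, f)
  canc <- depSpectrum(arms$cancer@centre, med, f)
  expect_length(ctrl, 20L)
  expect_true(all(ctrl >= -0.5 & ctrl <= 1))
  # composition identity
  expect_identical(ctrl, reCM(arms$control@centre, med, f))
  # cancer-like cells: more negative below the crossover (~80 kHz),
  # more positive above 100 kHz
  expect_true(all(canc[f < 8e4] < ctrl[f < 8e4]))
  expect_true(all(canc[f > 1e5] > ctrl[f > 1e5]))
  expect_error(depSpectrum(arms$control@centre, med, numeric(0)), "empty")
})

test_that("crossover root finding matches the thin-shell closed form", {
  med <- refMedium()
  # conductive cytoplasm (sigma_cyt >> sigma_medium), insulating membrane
  cell <- ShellParams(10e-6, 0.01, 0, 60, 1.0)
  cf <- crossoverClosedForm(cell, med)
  expect_equal(cf, oracleCrossoverClosedForm(10e-6, 0.01, 0.043))
  expect_equal(cf, 9.68e4, tolerance = 0.005)
  xo <- crossoverFrequency(cell, med)
  expect_true(xo$found)
  expect_lt(abs(xo$frequency - cf) / cf, 0.05)
  # 1/r scaling of the closed form, mirrored by the root
  cell2 <- ShellParams(20e-6, 0.01, 0, 60, 1.0)
  expect_equal(crossoverClosedForm(cell2, med), cf / 2)
  xo2 <- crossoverFrequency(cell2, med)
  expect_lt(abs(xo2$frequency - cf / 2) / (cf / 2), 0.05)
  # zero contrast: no crossover, reported not thrown
  d <- 1e-12
  same <- ShellParams(10e-6, 8.854e-12 * 78 / d, 0.043 / d, 78, 0.043)
  none <- crossoverFrequency(same, med)
  expect_false(none$found)
  expect_match(none$message, "no crossover")
})

test_that("noise-free spectra are exactly invertible by the fitter", {
  med <- refMedium()
  f <- defaultGrid()
  truth <- ShellParams(10e-6, 0.01, 2000, 60, 0.25)
  y <- depSpectrum(truth, med, f)
  # initialised at truth: residual stays ~0
  atTruth <- fitShellParams(f, y, med, truth)
  expect_true(atTruth$converged)
  expect_lt(atTruth$residualNorm, 1e-8)
  # initialised 2x off in membrane capacitance and cytoplasm conductivity
  init <- ShellParams(10e-6, 0.02, 2000, 60, 0.5)
  fit <- fitShellParams(f, y, med, init)
  expect_true(fit$converged)
  expect_lt(abs(fit$params@membraneCapacitance - 0.01) / 0.01, 0.01)
  expect_lt(abs(fit$params@cytoplasmConductivity - 0.25) / 0.25, 0.01)
  expect_lt(abs(fit$params@membraneConductance - 2000) / 2000, 0.01)
  # masked points are ignored: corrupt one masked point, fit unchanged
  y2 <- y; y2[7] <- 99
  mask <- rep(TRUE, 20); mask[7] <- FALSE
  fit2 <- fitShellParams(f, y2, med, init, mask = mask)
  expect_lt(abs(fit2$params@membraneCapacitance - 0.01) / 0.01, 0.01)
  # too few valid points for the free parameters
  expect_error(
    fitShellParams(f[1:2], y[1:2], med, init),
    "free parameters")
})
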