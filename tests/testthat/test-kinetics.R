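test_that("background subtraction is pointwise, clipped and gain-aware", {
  t <- seq(0, 100, by = 5)
  blank <- kineticTrace("blank", t, rep(0.04, length(t)), rep(30, length(t)), 50)
  tr <- kineticTrace("w", t, rep(0.04, length(t)), rep(30, length(t)), 50)
  cor1 <- subtractBackgrounds(tr, blank, blank)
  expect_true(all(cor1@od600 == 0))
  expect_true(all(cor1@fluorescence == 0))
  expect_identical(cor1@nClipped, 0L)
  expect_true(cor1@corrected)

  # known signal on top of backgrounds is recovered exactly (noiseless)
  sig <- seq(0, 50, length.out = length(t))
  tr2 <- kineticTrace("w2", t, 0.04 + 0.1 * seq_along(t) / length(t),
                      30 + sig, 50)
  cor2 <- subtractBackgrounds(tr2, blank, blank)
  expect_equal(cor2@fluorescence, sig, tolerance = 1e-12)

  # different background gain needs a calibration, then rescales exactly
  calib <- noiselessCalibration()
  nf70 <- kineticTrace("nf", t, rep(0.04, length(t)),
                       rep(30, length(t)) * gainFactor(70), 70)
  expect_error(subtractBackgrounds(tr2, blank, nf70), "calibration error")
  cor3 <- subtractBackgrounds(tr2, blank, nf70, calib)
  expect_equal(cor3@fluorescence, sig, tolerance = 1e-9)

  # negative results are clipped and counted
  lowF <- kineticTrace("w3", t, rep(0.02, length(t)), rep(10, length(t)), 50)
  cor4 <- subtractBackgrounds(lowF, blank, blank)
  expect_true(all(cor4@od600 == 0) && all(cor4@fluorescence == 0))
  expect_identical(cor4@nClipped, 2L * length(t))
})

test_that("background traces align by interpolation within tolerance only", {
  t <- seq(0, 100, by = 5)
  tr <- kineticTrace("w", t, rep(0.1, length(t)), rep(50, length(t)), 50)
  tOff <- t + 1  # < half the sampling interval
  blankOff <- kineticTrace("b", tOff, rep(0.04, length(tOff)),
                           rep(30, length(tOff)), 50)
  corrected <- subtractBackgrounds(tr, blankOff, blankOff)
  expect_equal(corrected@od600, rep(0.06, length(t)), tolerance = 1e-12)
  tFar <- t + 4  # beyond half the interval
  blankFar <- kineticTrace("b", tFar, rep(0.04, length(tFar)),
                           rep(30, length(tFar)), 50)
  expect_error(subtractBackgrounds(tr, blankFar, blankFar), "alignment error")
})

test_that("exponential-phase detection recovers a pure exponential exactly", {
  t <- seq(0, 300, by = 5)
  m <- log(2) / 86
  tr <- kineticTrace("w", t, 0.03 * exp(m * t), rep(0, length(t)), 50)
  tr@corrected <- TRUE
  g <- detectExponentialPhase(tr)
  expect_equal(doublingTime(g), 86, tolerance = 1e-9)
  expect_equal(g@r2, 1, tolerance = 1e-9)
  # doubling time is invariant to rescaling OD
  tr2 <- kineticTrace("w", t, 5 * tr@od600, rep(0, length(t)), 50)
  expect_equal(doublingTime(detectExponentialPhase(tr2)), 86,
               tolerance = 1e-9)
})

test_that("detection excludes lag and plateau of a saturating curve", {
  t <- seq(0, 480, by = 5)
  od <- piecewiseGrowth(t, rate = log(2) / 59)
  tr <- kineticTrace("w", t, od, rep(0, length(t)), 50)
  g <- detectExponentialPhase(tr)
  # the boundary point at t = lag lies on both segments; require the window
  # to start past every strictly-flat lag point
  lagEndIdx <- max(which(t < 40))
  expect_gt(g@windowStart, lagEndIdx)
  expect_lt(t[g@windowEnd], t[which.max(od)])
  expect_equal(doublingTime(g), 59, tolerance = 1e-6)
})

test_that("degenerate traces raise detection errors", {
  t <- seq(0, 200, by = 5)
  flat <- kineticTrace("w", t, rep(0.2, length(t)), rep(0, length(t)), 50)
  expect_error(detectExponentialPhase(flat), "detection error")
  few <- kineticTrace("w", t, c(rep(0.005, length(t) - 5), rep(0.3, 5)),
                      rep(0, length(t)), 50)
  expect_error(detectExponentialPhase(few), "detection error")
})

test_that("S_cell estimation matches the generator truth and honors gain", {
  d <- characterizationDesign(conditions = "MC", doses = c(0, 100),
                              clones = 1, noise = FALSE)
  sim <- simulatePlate(d, seed = 1)
  calib <- noiselessCalibration()
  blank <- wellTrace(sim$kinetics, "blank")
  nonfluo <- wellTrace(sim$kinetics, "nonfluo")
  tr <- subtractBackgrounds(wellTrace(sim$kinetics, "101_RFP.MC.c1"),
                            blank, nonfluo, calib)
  g <- detectExponentialPhase(tr)
  sc <- estimateScell(tr, g, calib, inductionTime = 0)
  truth <- sim$manifest$scell_true[sim$manifest$well_id == "101_RFP.MC.c1"]
  expect_lt(relErr(scellValue(sc), truth), 1e-2)
  # averaging window starts at least 50 min post induction
  expect_gte(sc@windowStart, 50)

  # constant fluorescence means zero synthesis
  tfl <- kineticTrace("w", tr@time, tr@od600, rep(7, length(tr@time)), 50)
  tfl@corrected <- TRUE
  expect_equal(scellValue(estimateScell(tfl, g, calib, inductionTime = 0)), 0)
})

test_that("gain-50 normalization makes S_cell gain-invariant", {
  t <- seq(0, 480, by = 5)
  od <- piecewiseGrowth(t, rate = log(2) / 60)
  cumint <- c(0, cumsum((od[-1] + od[-length(od)]) / 2 * diff(t)))
  calib <- noiselessCalibration()
  scTrue <- 12
  vals <- vapply(c(50, 70), function(g) {
    tr <- kineticTrace("w", t, od, scTrue * cumint * gainFactor(g), g)
    tr@corrected <- TRUE
    gr <- detectExponentialPhase(tr)
    scellValue(estimateScell(tr, gr, calib, inductionTime = 0))
  }, numeric(1L))
  expect_lt(relErr(vals[2], vals[1]), 1e-6)
})

test_that("gain calibration fitting is ratio-based and guarded", {
  cal <- fitGainCalibration(data.frame(gain = c(50, 100),
                                       reading = c(100, 1000)))
  expect_equal(calibrationFactor(cal, 100), 10)
  expect_equal(calibrationFactor(cal, 50), 1)
  s <- simulateCalibrationSeries(noiseSd = 0)
  cal2 <- fitGainCalibration(s)
  expect_equal(cal2@factors, gainFactor(cal2@gains), tolerance = 1e-12)
  expect_error(fitGainCalibration(data.frame(gain = c(60, 70),
                                             reading = c(1, 2))),
               "calibration error")
  expect_warning(
    calNM <- fitGainCalibration(data.frame(gain = c(50, 60, 70),
                                           reading = c(100, 300, 200))),
    "not strictly increasing")
  expect_false(calNM@monotone)
  expect_error(calibrationFactor(cal2, 120), "calibration error")
})
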