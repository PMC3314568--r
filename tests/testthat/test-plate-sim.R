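test_that("gain response is anchored at 50 and strictly increasing", {
  expect_identical(gainFactor(50), 1)
  expect_gt(gainFactor(70), gainFactor(60))
  g <- seq(50, 100, by = 5)
  expect_true(all(diff(gainFactor(g)) > 0))
  expect_error(gainFactor(40), "out of range")
  expect_error(gainFactor(110), "out of range")
  v <- 123.4
  expect_equal(v * gainFactor(80) / gainFactor(80), v)
})

test_that("calibration series reproduces the gain response and is seeded", {
  s <- simulateCalibrationSeries(noiseSd = 0)
  expect_identical(s$gain, c(50, 60, 70, 80, 90, 100))
  expect_equal(s$reading / s$reading[s$gain == 50], gainFactor(s$gain),
               tolerance = 1e-12)
  expect_identical(simulateCalibrationSeries(seed = 11),
                   simulateCalibrationSeries(seed = 11))
  expect_false(identical(simulateCalibrationSeries(seed = 11),
                         simulateCalibrationSeries(seed = 12)))
  expect_error(simulateCalibrationSeries(gains = c(60, 70)), "calibration error")
})

test_that("constitutive steady-state rate is n * rho * r / d", {
  expect_equal(constitutiveScell(n = 3, r = 2, d = 0.1, rho = 0.05),
               3 * 0.05 * 2 / 0.1)
  expect_equal(constitutiveScell(2, 1, 0.2, 0.1),
               2 * constitutiveScell(1, 1, 0.2, 0.1))
})

test_that("plate simulation is deterministic and controls are signal-free", {
  d <- characterizationDesign(conditions = "MC", doses = c(0, 100),
                              clones = 1)
  s1 <- simulatePlate(d, seed = 5)
  s2 <- simulatePlate(d, seed = 5)
  expect_identical(SummarizedExperiment::assay(s1$kinetics, "fluorescence"),
                   SummarizedExperiment::assay(s2$kinetics, "fluorescence"))
  expect_identical(s1$manifest, s2$manifest)

  d0 <- characterizationDesign(conditions = "MC", doses = c(0, 100),
                               clones = 1, noise = FALSE)
  s0 <- simulatePlate(d0, seed = 1)
  blank <- wellTrace(s0$kinetics, "blank")
  # blank fluorescence is the constant medium background at its gain
  expect_equal(blank@fluorescence,
               rep(gainFactor(blank@gain) * 30, length(blank@time)))
  expect_true(all(blank@od600 == blank@od600[1L]))
  # simulated OD minus blank is non-negative at all times, for every well
  odm <- SummarizedExperiment::assay(s0$kinetics, "od600")
  expect_true(all(sweep(odm, 2, blank@od600) >= 0))
})

test_that("zero-noise pipeline recovers every manifest parameter within 1%", {
  d <- characterizationDesign(conditions = "SC", clones = 1, noise = FALSE)
  res <- runCharacterization(seed = 2, design = d)
  sim <- simulatePlate(d, seed = 2)
  m <- merge(res$wells, sim$manifest[, c("well_id", "scell_true",
                                         "doubling_time")], by = "well_id")
  # relative recovery within the study's measured range (>= 0.5 AU/min/cell);
  # wells far below it are checked on the absolute scale (the residual
  # background-mismatch error is additive, not proportional)
  bright <- m$scell_true >= 0.5
  dim <- !is.na(m$scell_true) & m$scell_true < 0.5
  expect_lt(max(relErr(m$scell_gain50[bright], m$scell_true[bright])), 1e-2)
  expect_lt(max(abs(m$scell_gain50[dim] - m$scell_true[dim])), 0.01)
  expect_lt(max(relErr(m$doubling_time_min, m$doubling_time)), 1e-2)
  truth <- sim$truth$SC
  # RPU at full induction
  top <- res$inductionCurves$SC
  expect_lt(relErr(top$rpu[which.max(top$dose_nM)],
                   truth$scell_hsl$rpu[which.max(truth$scell_hsl$dose_nM)]),
            1e-2)
  est <- res$estimatesTable
  expect_lt(relErr(est$vmax, truth$vmax_rpu), 1e-2)
  expect_lt(relErr(est$kA, truth$params@KA), 1e-2)
  expect_lt(relErr(est$nA, truth$params@nA), 1e-2)
  expect_lt(relErr(est$alpha_lux, truth$params@alphaLux), 1e-2)
})

test_that("noisy recovery is unbiased over 20 seeds at default noise", {
  d <- characterizationDesign(conditions = "MC", doses = c(0, 100),
                              clones = 1)
  calib <- noiselessCalibration()
  errs <- vapply(1:20, function(s) {
    sim <- simulatePlate(d, seed = s)
    w <- processPlate(sim$kinetics, calib, inductionTime = 0)
    m <- merge(w, sim$manifest[, c("well_id", "scell_true", "doubling_time")],
               by = "well_id")
    pos <- m$scell_true > 0
    c(scSigned = mean(m$scell_gain50[pos] / m$scell_true[pos] - 1),
      dtAbs = median(abs(m$doubling_time_min / m$doubling_time - 1)),
      scAbs = median(abs(m$scell_gain50[pos] / m$scell_true[pos] - 1)))
  }, numeric(3L))
  expect_lt(abs(mean(errs["scSigned", ])), 0.05)   # unbiasedness
  expect_lt(median(errs["dtAbs", ]), 0.02)         # doubling time < 2%
  expect_lt(median(errs["scAbs", ]), 0.05)         # S_cell < 5%
})
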