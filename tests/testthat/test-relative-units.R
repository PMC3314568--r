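test_that("RPU is the gain-matched S_cell ratio with pairing guards", {
  expect_equal(rpu(0.69, 0.69), 1)
  expect_equal(rpu(0.54, 0.69), 0.783, tolerance = 1e-3)
  expect_error(rpu(1, 1, condition = "SC", conditionRef = "HC"),
               "pairing error")
  expect_error(rpu(1, 0), "reference error")
  # invariance to a common fluorescence-unit rescaling
  expect_equal(rpu(7 * 0.54, 7 * 0.69), rpu(0.54, 0.69), tolerance = 1e-12)
})

test_that("copy-number ratios round to the published integer estimates", {
  sc <- referenceScell()
  v101 <- with(sc[sc$device == "101_RFP", ], setNames(scell, condition))
  est101 <- copyNumberEstimate(v101)
  expect_equal(est101$estimate[est101$condition == "HC"], 128)
  expect_equal(est101$estimate[est101$condition == "LC"], 4)
  expect_equal(est101$estimate[est101$condition == "SC"], 1)
  vIQ <- with(sc[sc$device == "IQ_RFP", ], setNames(scell, condition))
  estIQ <- copyNumberEstimate(vIQ)
  expect_equal(estIQ$estimate[estIQ$condition == "MC"], 42)
  expect_equal(estIQ$estimate[estIQ$condition == "LC"], 4)
  expect_error(copyNumberEstimate(c(HC = 88.36)), "baseline error")
})

test_that("unrounded mean copy numbers reproduce the model inputs", {
  sc <- referenceScell()
  est <- do.call(rbind, lapply(split(sc, sc$device), function(d) {
    cbind(device = d$device[1L],
          copyNumberEstimate(setNames(d$scell, d$condition)))
  }))
  m <- meanCopyNumber(est)
  expect_equal(m[["HC"]], mean(c(88.36 / 0.69, 59.1 / 0.54)),
               tolerance = 1e-12)
  expect_equal(m[["HC"]], 118.75, tolerance = 1e-4)
  expect_equal(m[["SC"]], 1)
  single <- meanCopyNumber(data.frame(device = "101_RFP", condition = "MC",
                                      ratio = 49.565))
  expect_equal(single[["MC"]], 49.565)
  expect_error(meanCopyNumber(data.frame()), "empty input")
})

test_that("scar correction divides by the factor and inverts", {
  expect_equal(scarCorrectedRpu(0.783, 1.0), 0.783)
  expect_equal(scarCorrectedRpu(0.783), 0.548, tolerance = 1e-3)
  x <- 1.234
  expect_equal(scarCorrectedRpu(x, 1.43) * 1.43, x, tolerance = 1e-12)
  expect_error(scarCorrectedRpu(1, 0), "positive")
})

test_that("condition summaries use a t-based 95% CI over clones", {
  s <- summarizeCondition(c(1, 1, 1))
  expect_equal(s$ci95, 0)
  expect_equal(s$mean, 1)
  expect_error(summarizeCondition(2), "summary error")
  s3 <- summarizeCondition(c(0.9, 1.0, 1.1))
  expect_equal(s3$ci95, qt(0.975, 2) * sd(c(0.9, 1, 1.1)) / sqrt(3),
               tolerance = 1e-12)
})

test_that("lacIQ relative activity averages to the published grand mean", {
  sc <- referenceScell()
  perCond <- vapply(c("SC", "LC", "MC", "HC"), function(cc) {
    rpu(sc$scell[sc$device == "IQ_RFP" & sc$condition == cc],
        sc$scell[sc$device == "101_RFP" & sc$condition == cc], cc, cc)
  }, numeric(1L))
  expect_equal(mean(perCond), 0.744, tolerance = 1e-3)
})

test_that("clone-level CIs cover the true RPU in at least 90% of seeds", {
  wells <- data.frame(
    well_id = c(sprintf("101_RFP.MC.c%d", 1:3), sprintf("IQ_RFP.MC.c%d", 1:3),
                "blank", "nonfluo"),
    device = c(rep("101_RFP", 3), rep("IQ_RFP", 3), "blank", "nonfluo"),
    condition = c(rep("MC", 6), NA, NA),
    dose_nM = NA_real_, clone = c(1:3, 1:3, NA, NA), gain = 60,
    scell_true = c(rep(34.2, 3), rep(22.7, 3), NA, NA),
    growth_rate = log(2) / c(rep(59, 3), rep(65, 3), 38, 38),
    lag_min = 40, capacity = 0.5, od0 = 0.03, stringsAsFactors = FALSE)
  d <- plateDesign(wells)
  calib <- noiselessCalibration()
  trueRpu <- 22.7 / 34.2
  covered <- vapply(1:100, function(s) {
    sim <- simulatePlate(d, seed = s)
    w <- processPlate(sim$kinetics, calib, inductionTime = 0)
    perClone <- vapply(1:3, function(cl) {
      rpu(w$scell_gain50[w$device == "IQ_RFP" & w$clone == cl],
          w$scell_gain50[w$device == "101_RFP" & w$clone == cl])
    }, numeric(1L))
    s3 <- summarizeCondition(perClone)
    abs(s3$mean - trueRpu) <= s3$ci95
  }, logical(1L))
  expect_gte(mean(covered), 0.90)
})

test_that("full-induction RPU is flat across conditions when saturation is off", {
  d <- characterizationDesign(conditions = c("SC", "MC", "HC"),
                              doses = c(0, 0.5, 5, 50, 1000), clones = 1,
                              idealized = TRUE, saturation = FALSE)
  res <- runCharacterization(seed = 4, design = d)
  top <- vapply(res$inductionCurves,
                function(cc) cc$rpu[which.max(cc$dose_nM)], numeric(1L))
  expect_lt(max(top) / min(top) - 1, 1e-2)
})
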