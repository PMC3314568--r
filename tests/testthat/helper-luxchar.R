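# shared fixtures for the suite; everything is generated in code

relErr <- function(est, truth) abs(est / truth - 1)

# noiseless gain calibration matching the generator's default response
noiselessCalibration <- function(slope = 0.02) {
  fitGainCalibration(simulateCalibrationSeries(noiseSd = 0, slope = slope))
}

# analytic RPU-vs-HSL curve for one condition from the published
# transfer-function parameters (the round-trip generating truth)
publishedRpuCurve <- function(condition,
                              doses = c(0, 10^seq(-2, 3, length.out = 12))) {
  hrow <- referenceHillEstimates()
  hrow <- hrow[hrow$condition == condition, ]
  n <- referenceCopyNumbers()[[condition]]
  ax <- transformAxis(doses, n, luxModelParameters())
  vmax <- hrow$vmax
  rpu <- vmax / (1 + (hrow$kA / pmax(ax$A, .Machine$double.xmin))^hrow$nA)
  rpu[ax$A == 0] <- 0
  data.frame(dose_nM = doses, A = ax$A, rpu = rpu,
             vmax = vmax, kA = hrow$kA, nA = hrow$nA, n = n)
}

# small piecewise growth curve mirroring the generator's construction
piecewiseGrowth <- function(t, od0 = 0.03, rate = log(2) / 86, lag = 40,
                            capacity = 0.5) {
  odSwitch <- 0.6 * capacity
  t1 <- lag + log(odSwitch / od0) / rate
  kTail <- rate * 0.6 / 0.4
  od <- numeric(length(t))
  od[t <= lag] <- od0
  mid <- t > lag & t <= t1
  od[mid] <- od0 * exp(rate * (t[mid] - lag))
  late <- t > t1
  od[late] <- capacity - (capacity - odSwitch) * exp(-kTail * (t[late] - t1))
  od
}
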