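.DEVICE_LABELS <- c("HSL_RFP", "101_RFP", "IQ_RFP", "blank", "nonfluo")

#' Microplate experiment design
#'
#' Describes every well of a simulated plate (device, copy-number condition,
#' HSL dose, clone, detector gain, growth model and true per-cell synthesis
#' rate) together with the acquisition protocol and the noise model. A valid
#' plate carries exactly one medium blank and one non-fluorescent-strain well,
#' the two dedicated background controls.
#'
#' @slot wells data.frame with columns \code{well_id}, \code{device} (one of
#'   HSL_RFP, 101_RFP, IQ_RFP, blank, nonfluo), \code{condition},
#'   \code{dose_nM}, \code{clone}, \code{gain}, \code{scell_true} (gain-50 AU
#'   min^-1 cell^-1; NA for controls), \code{growth_rate} (min^-1),
#'   \code{lag_min}, \code{capacity}, \code{od0}.
#' @slot samplingInterval acquisition interval (min), default 5.
#' @slot horizon kinetic-cycle length (min).
#' @slot inductionTime time at which HSL is added (min); inducible wells
#'   express from this time on.
#' @slot gainSlope k in the generator's gain response 10^(k (gain - 50)).
#' @slot noiseOD additive Gaussian sd on OD600.
#' @slot noiseFluo additive Gaussian sd on fluorescence, in AU at gain 50
#'   (scaled by the gain factor at acquisition).
#' @slot odBackground absorbance of the medium (added to every well).
#' @slot mediumFluo fluorescence of the medium in AU at gain 50.
#' @slot autofluoPerOD cell autofluorescence per OD600 unit, AU at gain 50.
#' @slot cloneSdLog sd (log scale) of the clone-level multiplicative
#'   perturbation of the true S_cell.
#' @slot modelTruth list of per-condition generating parameters (filled by
#'   [characterizationDesign()]), used by the ground-truth manifest.
#' @exportClass PlateDesign
setClass("PlateDesign",
  representation(
    wells = "data.frame", samplingInterval = "numeric", horizon = "numeric",
    inductionTime = "numeric", gainSlope = "numeric",
    noiseOD = "numeric", noiseFluo = "numeric",
    odBackground = "numeric", mediumFluo = "numeric",
    autofluoPerOD = "numeric", cloneSdLog = "numeric",
    modelTruth = "list"
  )
)

setValidity("PlateDesign", function(object) {
  msgs <- character()
  w <- object@wells
  need <- c("well_id", "device", "condition", "dose_nM", "clone", "gain",
            "scell_true", "growth_rate", "lag_min", "capacity", "od0")
  miss <- setdiff(need, colnames(w))
  if (length(miss))
    return(paste0("wells lacks column(s): ", paste(miss, collapse = ", ")))
  bad <- setdiff(unique(w$device), .DEVICE_LABELS)
  if (length(bad))
    msgs <- c(msgs, paste0("unknown device label(s): ",
                           paste(bad, collapse = ", ")))
  if (sum(w$device == "blank") != 1L)
    msgs <- c(msgs, "exactly one medium-blank well is required")
  if (sum(w$device == "nonfluo") != 1L)
    msgs <- c(msgs, "exactly one non-fluorescent-strain well is required")
  if (anyDuplicated(w$well_id))
    msgs <- c(msgs, "well_id values must be unique")
  if (any(w$gain < 50 | w$gain > 100))
    msgs <- c(msgs, "gains must lie in [50, 100]")
  if (any(w$dose_nM < 0, na.rm = TRUE))
    msgs <- c(msgs, "doses must be non-negative")
  if (object@samplingInterval <= 0 || object@horizon <= 0)
    msgs <- c(msgs, "samplingInterval and horizon must be positive")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PlateDesign", function(object) {
  w <- object@wells
  cat(sprintf("PlateDesign: %d wells (%d measurement, 2 controls)\n",
              nrow(w), sum(!w$device %in% c("blank", "nonfluo"))))
  cat(sprintf("  sampling every %g min over %g min; induction at %g min\n",
              object@samplingInterval, object@horizon, object@inductionTime))
  cat(sprintf("  noise: OD sd %g, fluorescence sd %g AU (gain-50); clone sdlog %g\n",
              object@noiseOD, object@noiseFluo, object@cloneSdLog))
  invisible(NULL)
})

#' Construct a plate design from a well table
#'
#' @param wells see the \code{wells} slot of [PlateDesign-class].
#' @param samplingInterval,horizon,inductionTime acquisition protocol (min).
#' @param gainSlope generator gain-response slope (factor = 10^(k (g - 50))).
#' @param noiseOD,noiseFluo additive measurement-noise sds.
#' @param odBackground,mediumFluo,autofluoPerOD background model.
#' @param cloneSdLog clone-level lognormal perturbation sd.
#' @param modelTruth optional list of generating parameters per condition.
#' @return A [PlateDesign-class] object.
#' @export
plateDesign <- function(wells, samplingInterval = 5, horizon = 480,
                        inductionTime = 0, gainSlope = 0.02,
                        noiseOD = 0.002, noiseFluo = 0.5,
                        odBackground = 0.04, mediumFluo = 30,
                        autofluoPerOD = 0.2, cloneSdLog = 0.05,
                        modelTruth = list()) {
  new("PlateDesign",
    wells = as.data.frame(wells), samplingInterval = samplingInterval,
    horizon = horizon, inductionTime = inductionTime, gainSlope = gainSlope,
    noiseOD = noiseOD, noiseFluo = noiseFluo, odBackground = odBackground,
    mediumFluo = mediumFluo, autofluoPerOD = autofluoPerOD,
    cloneSdLog = cloneSdLog, modelTruth = modelTruth
  )
}

#' Steady-state per-cell synthesis rate of a constitutive device
#'
#' For the two-stage constitutive expression model (mRNA M, protein P):
#' dM/dt = n r - d M, dP/dt = rho M - gamma P, the steady-state mRNA level is
#' n r / d and the per-cell protein synthesis rate -- the quantity S_cell
#' measures -- is \eqn{n \rho r / d}. The generator parameterizes
#' constitutive wells directly by this composite rate (\code{scell_true});
#' this helper exposes the identity for building designs from mechanistic
#' rates.
#'
#' @param n DNA copies per cell.
#' @param r mRNA synthesis rate per DNA copy (AU min^-1).
#' @param d mRNA degradation rate (min^-1).
#' @param rho protein synthesis rate per mRNA (min^-1).
#' @return S_cell in AU min^-1 cell^-1.
#' @export
constitutiveScell <- function(n, r, d, rho) {
  stopifnot(n >= 0, r > 0, d > 0, rho > 0)
  n * rho * r / d
}

#' Detector gain response of the generator
#'
#' Multiplicative fluorescence factor relative to gain 50, modeled as
#' \eqn{10^{k (g - 50)}} with default k = 0.02 (so gain 100 reads 10x gain
#' 50). Any strictly monotone form would do: the analysis pipeline consumes
#' only empirical calibration ratios, never this parametric form.
#'
#' @param gain gain value(s) in [50, 100].
#' @param slope k, default 0.02.
#' @return Factor(s) >= 1; exactly 1 at gain 50.
#' @export
gainFactor <- function(gain, slope = 0.02) {
  if (any(is.na(gain)) || any(gain < 50 | gain > 100))
    stop("gain out of range: must lie in [50, 100]")
  10^(slope * (gain - 50))
}

#' Simulated gain calibration series
#'
#' Emulates the calibration protocol: a fixed bright sample measured once at
#' each gain. Readings equal trueValue x gainFactor(gain) plus gain-scaled
#' additive noise.
#'
#' @param gains gains to measure; must include 50 (the normalization anchor)
#'   and lie in [50, 100]. Default \code{c(50, 60, 70, 80, 90, 100)}.
#' @param seed integer seed fixing the noise.
#' @param trueValue noiseless reading at gain 50 (AU), default 2000.
#' @param noiseSd additive noise sd at gain 50, default 0.5.
#' @param slope generator gain-response slope.
#' @return data.frame with columns \code{gain}, \code{reading}.
#' @export
simulateCalibrationSeries <- function(gains = c(50, 60, 70, 80, 90, 100),
                                      seed = 1L, trueValue = 2000,
                                      noiseSd = 0.5, slope = 0.02) {
  if (!50 %in% gains)
    stop("calibration error: gain 50 (the anchor) must be measured")
  gf <- gainFactor(gains, slope)
  set.seed(as.integer(seed))
  data.frame(gain = gains,
             reading = trueValue * gf + rnorm(length(gains), 0, noiseSd) * gf)
}

# Growth trajectory: flat lag, then exact exponential at `rate` up to
# 0.6 * capacity, then exponential approach to capacity with slope-continuous
# matching. The exponential segment is exactly log-linear by construction, so
# the downstream window detector has a well-defined truth.
.growthCurve <- function(t, od0, rate, lag, capacity, switchFrac = 0.6) {
  odSwitch <- switchFrac * capacity
  if (od0 >= odSwitch)
    stop("od0 must be below the exponential/saturation switch point")
  t1 <- lag + log(odSwitch / od0) / rate
  kTail <- rate * switchFrac / (1 - switchFrac)  # slope continuity at t1
  od <- numeric(length(t))
  od[t <= lag] <- od0
  mid <- t > lag & t <= t1
  od[mid] <- od0 * exp(rate * (t[mid] - lag))
  late <- t > t1
  od[late] <- capacity - (capacity - odSwitch) * exp(-kTail * (t[late] - t1))
  od
}

# Cumulative integral of OD from `start` evaluated at acquisition times,
# computed on a 10x finer trapezoid grid.
.cumODIntegral <- function(times, start, od0, rate, lag, capacity, dtFine) {
  tf <- seq(min(start, times[1L]), max(times), by = dtFine)
  odf <- .growthCurve(tf, od0, rate, lag, capacity)
  ct <- c(0, cumsum((odf[-1L] + odf[-length(odf)]) / 2 * diff(tf)))
  at <- function(x) approx(tf, ct, xout = x, rule = 2)$y
  pmax(at(times) - at(start), 0) * (times >= start)
}

#' Simulate a microplate kinetic experiment
#'
#' Generates the raw kinetic export the analysis pipeline consumes: per-well
#' time series of raw OD600 (medium absorbance + culture OD + noise) and raw
#' fluorescence (gain-scaled medium background + OD-proportional cell
#' autofluorescence + reporter signal + noise), plus a ground-truth manifest.
#'
#' The reporter signal per well follows the dilution-matched accumulation
#' construction: with per-cell synthesis rate S and dilution equal to the
#' instantaneous growth rate, total well fluorescence obeys dF/dt = S x OD, so
#' F(t) = S x integral of OD from expression onset (induction time for the
#' inducible device, culture start otherwise). The downstream derivative
#' estimator dF/dt / OD therefore has exact truth S at every timepoint of the
#' growth curve.
#'
#' Clone-to-clone variability multiplies the true S_cell of every well of a
#' (device, condition, clone) group by a shared lognormal factor. The manifest
#' records the realized (post-clone-factor) truth.
#'
#' @param design a [PlateDesign-class].
#' @param seed integer; fixes all randomness (clone factors, then noise).
#' @return list with elements \code{kinetics} (a [PlateKinetics-class]),
#'   \code{manifest} (data.frame of per-well ground truth: realized
#'   \code{scell_true} at gain 50, \code{growth_rate}, \code{doubling_time},
#'   exponential-segment bounds) and \code{truth} (the design's per-condition
#'   generating parameters).
#' @examples
#' d <- characterizationDesign(conditions = "MC", doses = c(0, 100), clones = 1)
#' sim <- simulatePlate(d, seed = 1)
#' sim$kinetics
#' @export
simulatePlate <- function(design, seed = 1L) {
  stopifnot(is(design, "PlateDesign"))
  validObject(design)
  set.seed(as.integer(seed))
  w <- design@wells
  times <- seq(0, design@horizon, by = design@samplingInterval)
  nt <- length(times)
  dtFine <- design@samplingInterval / 10

  # clone-level multiplicative factors, shared across doses of a clone
  grp <- interaction(w$device, w$condition, w$clone, drop = TRUE)
  isMeas <- !w$device %in% c("blank", "nonfluo")
  fac <- setNames(rep(1, nlevels(grp)), levels(grp))
  if (design@cloneSdLog > 0) {
    measLv <- unique(as.character(grp[isMeas]))
    fac[measLv] <- rlnorm(length(measLv), 0, design@cloneSdLog)
  }
  cloneFactor <- fac[as.character(grp)]

  od <- matrix(0, nrow(w), nt)
  fl <- matrix(0, nrow(w), nt)
  scellReal <- rep(NA_real_, nrow(w))
  for (i in seq_len(nrow(w))) {
    dev <- w$device[i]
    odTrue <- if (dev == "blank") rep(0, nt) else
      .growthCurve(times, w$od0[i], w$growth_rate[i], w$lag_min[i],
                   w$capacity[i])
    signal <- rep(0, nt)
    if (isMeas[i]) {
      scellReal[i] <- w$scell_true[i] * cloneFactor[i]
      start <- if (dev == "HSL_RFP") design@inductionTime else 0
      signal <- scellReal[i] *
        .cumODIntegral(times, start, w$od0[i], w$growth_rate[i],
                       w$lag_min[i], w$capacity[i], dtFine)
    }
    gf <- gainFactor(w$gain[i], design@gainSlope)
    od[i, ] <- design@odBackground + odTrue +
      if (design@noiseOD > 0) rnorm(nt, 0, design@noiseOD) else 0
    fl[i, ] <- gf * (design@mediumFluo + design@autofluoPerOD * odTrue +
                       signal) +
      if (design@noiseFluo > 0) gf * rnorm(nt, 0, design@noiseFluo) else 0
  }

  kin <- plateKinetics(od, fl, times,
                       w[, c("well_id", "device", "condition", "dose_nM",
                             "clone", "gain")])
  manifest <- data.frame(
    w[, c("well_id", "device", "condition", "dose_nM", "clone", "gain")],
    scell_true = scellReal,
    growth_rate = ifelse(w$device == "blank", NA_real_, w$growth_rate),
    doubling_time = ifelse(w$device == "blank", NA_real_,
                           log(2) / w$growth_rate),
    exp_start_min = w$lag_min,
    exp_end_min = w$lag_min +
      log(0.6 * w$capacity / w$od0) / w$growth_rate,
    stringsAsFactors = FALSE
  )
  list(kinetics = kin, manifest = manifest, truth = design@modelTruth)
}

#' Full characterization plate design
#'
#' Builds the design the whole-study emulation uses: the two constitutive
#' devices (101_RFP reference and IQ_RFP) and the HSL-inducible device over a
#' dose range, replicated over clones, in each requested copy-number
#' condition, plus the two background control wells. Generating parameters
#' are the published characterization values ([referenceTables]): constitutive
#' S_cell and doubling times per device and condition, and the
#' activated-complex transfer function (alpha_lux, K_A, n_A with the
#' fixed LuxR/HSL constants) for the inducible device.
#'
#' @param conditions copy-number conditions to include, subset of
#'   \code{c("SC", "LC", "MC", "HC")}.
#' @param doses HSL dose grid (nM). Default: 0 plus 12 log-spaced doses in
#'   [0.01, 1000], covering basal through full induction.
#' @param clones biological replicates per device/condition, default 3.
#' @param noise logical; \code{FALSE} zeroes measurement noise and clone
#'   variability (the OD-proportional autofluorescence background stays on).
#' @param idealized logical; \code{TRUE} additionally zeroes the
#'   OD-proportional autofluorescence, leaving only backgrounds that control
#'   subtraction removes exactly. Used for round-trip oracle tests of the
#'   estimator path. Implies \code{noise = FALSE}.
#' @param saturation logical; \code{TRUE} (default) uses the per-condition
#'   published transfer functions, which embed the dose-limited saturation of
#'   high copy numbers. \code{FALSE} scales the single-copy parameters
#'   linearly with copy number (superposition world): full-induction RPU is
#'   then identical across conditions.
#' @param gains named gains per condition (brighter conditions at lower gain).
#' @param ... passed to [plateDesign()] (horizon, noise sds, backgrounds...).
#' @return A [PlateDesign-class] object with \code{modelTruth} filled.
#' @export
characterizationDesign <- function(conditions = c("SC", "LC", "MC", "HC"),
                                   doses = c(0, 10^seq(log10(0.01),
                                                       log10(1000),
                                                       length.out = 12)),
                                   clones = 3L, noise = TRUE,
                                   idealized = FALSE, saturation = TRUE,
                                   gains = c(SC = 100, LC = 80, MC = 60,
                                             HC = 50),
                                   ...) {
  if (idealized) noise <- FALSE
  conditions <- match.arg(conditions, c("SC", "LC", "MC", "HC"),
                          several.ok = TRUE)
  ns <- referenceCopyNumbers()
  sc <- referenceScell()
  dt <- referenceDoublingTimes()
  hill <- referenceHillEstimates()
  lag <- 40; od0 <- 0.03; capacity <- 0.5

  lookup <- function(df, dev, cond, col) {
    df[df$device == dev & df$condition == cond, col][1L]
  }
  scSC <- function(dev) lookup(sc, dev, "SC", "scell")

  rows <- list(); truth <- list()
  for (cond in conditions) {
    n <- unname(ns[cond])
    hrow <- hill[hill$condition == if (saturation) cond else "SC", ]
    pars <- luxModelParameters(n = n, alphaLux = hrow$alpha_lux,
                               KA = hrow$kA, nA = hrow$nA)
    Xss <- steadyStateLuxR(pars)
    A <- activatedComplex(doses, Xss, pars)
    scellHSL <- predictedScell(A, pars)
    refScell <- if (saturation) lookup(sc, "101_RFP", cond, "scell") else
      scSC("101_RFP") * n
    iqScell <- if (saturation) lookup(sc, "IQ_RFP", cond, "scell") else
      scSC("IQ_RFP") * n
    truth[[cond]] <- list(
      n = n, params = pars, scell_ref = refScell,
      vmax_rpu = pars@n * pars@alphaLux / refScell,
      scell_hsl = data.frame(dose_nM = doses, A = A, scell = scellHSL,
                             rpu = scellHSL / refScell)
    )
    g <- unname(gains[cond])
    for (cl in seq_len(clones)) {
      rows[[length(rows) + 1L]] <- data.frame(
        well_id = sprintf("%s.%s.c%d", c("101_RFP", "IQ_RFP"), cond, cl),
        device = c("101_RFP", "IQ_RFP"), condition = cond, dose_nM = NA_real_,
        clone = cl, gain = g, scell_true = c(refScell, iqScell),
        growth_rate = log(2) / c(lookup(dt, "101_RFP", cond, "doubling_min"),
                                 lookup(dt, "IQ_RFP", cond, "doubling_min")),
        lag_min = lag, capacity = capacity, od0 = od0,
        stringsAsFactors = FALSE
      )
      rows[[length(rows) + 1L]] <- data.frame(
        well_id = sprintf("HSL_RFP.%s.d%02d.c%d", cond, seq_along(doses), cl),
        device = "HSL_RFP", condition = cond, dose_nM = doses,
        clone = cl, gain = g, scell_true = scellHSL,
        growth_rate = log(2) / lookup(dt, "HSL_RFP", cond, "doubling_min"),
        lag_min = lag, capacity = capacity, od0 = od0,
        stringsAsFactors = FALSE
      )
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    well_id = c("blank", "nonfluo"), device = c("blank", "nonfluo"),
    condition = NA_character_, dose_nM = NA_real_, clone = NA_integer_,
    gain = 50, scell_true = NA_real_,
    growth_rate = log(2) / 38,  # typical host-strain doubling time
    lag_min = lag, capacity = capacity, od0 = od0, stringsAsFactors = FALSE
  )
  wells <- do.call(rbind, rows)
  extra <- list(...)
  args <- c(list(wells = wells, modelTruth = truth), extra)
  if (!noise) {
    args$noiseOD <- 0; args$noiseFluo <- 0; args$cloneSdLog <- 0
  }
  if (idealized) args$autofluoPerOD <- 0
  do.call(plateDesign, args)
}
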