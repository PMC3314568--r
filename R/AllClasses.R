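#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats approx cor median optim qt rlnorm rnorm sd setNames
#' @importFrom utils read.csv write.csv
NULL

.checkPositiveScalar <- function(x, name, allowNA = FALSE, allowZero = FALSE) {
  if (length(x) != 1L) return(sprintf("'%s' must be a single value", name))
  if (is.na(x)) {
    if (allowNA) return(NULL)
    return(sprintf("'%s' must not be NA", name))
  }
  if (!is.finite(x)) return(sprintf("'%s' must be finite", name))
  if (allowZero && x < 0) return(sprintf("'%s' must be >= 0", name))
  if (!allowZero && x <= 0) return(sprintf("'%s' must be > 0", name))
  NULL
}

#' Parameters of the steady-state model of the HSL-inducible device
#'
#' Holds every constant and estimated parameter of the LuxR/HSL activation
#' model: LuxR is synthesized constitutively from \code{n} DNA copies at rate
#' \code{alphaTet} per copy and degraded at rate \code{gammaX}; HSL binds LuxR
#' with dissociation constant \code{KH} and cooperativity \code{nH} to form the
#' activated complex A; A drives reporter synthesis with maximum per-copy rate
#' \code{alphaLux}, dissociation constant \code{KA} and cooperativity
#' \code{nA}; the reporter is diluted by growth at rate \code{mu}.
#'
#' "Per cell" quantities are operationally per OD600 unit throughout the
#' package, since population measurements proxy cell count by optical density.
#'
#' @slot n DNA copies per cell (dimensionless, \eqn{\ge 0}, not necessarily
#'   integer; 0 encodes the no-device degenerate case).
#' @slot alphaTet LuxR synthesis rate per cell per DNA copy
#'   (AU min\eqn{^{-1}} cell\eqn{^{-1}}).
#' @slot gammaX LuxR degradation rate (min\eqn{^{-1}}).
#' @slot KH dissociation constant of HSL-LuxR (nM).
#' @slot nH Hill cooperativity of HSL-LuxR binding (dimensionless).
#' @slot alphaLux maximum reporter synthesis rate per cell per DNA copy
#'   (AU min\eqn{^{-1}} cell\eqn{^{-1}}); \code{NA} until estimated.
#' @slot KA dissociation constant of the activated complex acting on the
#'   promoter (AU cell\eqn{^{-1}}); \code{NA} until estimated.
#' @slot nA Hill cooperativity of the activated complex on the promoter;
#'   \code{NA} until estimated.
#' @slot mu cell growth rate (min\eqn{^{-1}}); \code{NA} unless needed for
#'   dynamic simulation. May be fixed per condition by the caller.
#' @seealso [luxModelParameters()] for the user constructor with default
#'   constants.
#' @exportClass LuxModelParameters
setClass("LuxModelParameters",
  representation(
    n = "numeric", alphaTet = "numeric", gammaX = "numeric",
    KH = "numeric", nH = "numeric",
    alphaLux = "numeric", KA = "numeric", nA = "numeric",
    mu = "numeric"
  )
)

setValidity("LuxModelParameters", function(object) {
  msgs <- c(
    .checkPositiveScalar(object@n, "n", allowZero = TRUE),
    .checkPositiveScalar(object@alphaTet, "alphaTet"),
    .checkPositiveScalar(object@gammaX, "gammaX"),
    .checkPositiveScalar(object@KH, "KH"),
    .checkPositiveScalar(object@nH, "nH"),
    .checkPositiveScalar(object@alphaLux, "alphaLux", allowNA = TRUE),
    .checkPositiveScalar(object@KA, "KA", allowNA = TRUE),
    .checkPositiveScalar(object@nA, "nA", allowNA = TRUE),
    .checkPositiveScalar(object@mu, "mu", allowNA = TRUE, allowZero = TRUE)
  )
  if (length(msgs)) msgs else TRUE
})

#' Construct model parameters with the default constants
#'
#' Defaults for the fixed constants are the values used throughout the
#' characterization: \code{alphaTet = 2.3} AU min^-1 cell^-1,
#' \code{gammaX = 6e-2} min^-1, \code{KH = 553} nM, \code{nH = 2}.
#' Estimated parameters (\code{alphaLux}, \code{KA}, \code{nA}, \code{mu})
#' default to \code{NA} and must be supplied before operations that need them.
#'
#' @param n DNA copy number per cell (default 1, the single-copy condition).
#' @param alphaTet,gammaX,KH,nH fixed constants, see above.
#' @param alphaLux,KA,nA,mu estimated parameters, \code{NA} by default.
#' @return A [LuxModelParameters-class] object.
#' @examples
#' p <- luxModelParameters()
#' steadyStateLuxR(p)  # 38.33 AU/cell at single copy
#' @export
luxModelParameters <- function(n = 1, alphaTet = 2.3, gammaX = 6e-2,
                               KH = 553, nH = 2,
                               alphaLux = NA_real_, KA = NA_real_,
                               nA = NA_real_, mu = NA_real_) {
  new("LuxModelParameters",
    n = as.numeric(n), alphaTet = as.numeric(alphaTet),
    gammaX = as.numeric(gammaX), KH = as.numeric(KH), nH = as.numeric(nH),
    alphaLux = as.numeric(alphaLux), KA = as.numeric(KA),
    nA = as.numeric(nA), mu = as.numeric(mu)
  )
}

setMethod("show", "LuxModelParameters", function(object) {
  cat("LuxModelParameters\n")
  cat(sprintf("  n = %g copies/cell\n", object@n))
  cat(sprintf("  alphaTet = %g AU/min/cell, gammaX = %g /min\n",
              object@alphaTet, object@gammaX))
  cat(sprintf("  KH = %g nM, nH = %g\n", object@KH, object@nH))
  cat(sprintf("  alphaLux = %g AU/min/cell, KA = %g AU/cell, nA = %g\n",
              object@alphaLux, object@KA, object@nA))
  cat(sprintf("  mu = %g /min\n", object@mu))
  invisible(NULL)
})

#' One well's kinetic trace
#'
#' Raw (or background-corrected) OD600 and fluorescence time series for a
#' single microplate well at a stated detector gain.
#'
#' @slot wellId character well identifier.
#' @slot time acquisition times in minutes, strictly increasing.
#' @slot od600 optical density readings (same length as \code{time}).
#' @slot fluorescence fluorescence readings in AU at \code{gain}.
#' @slot gain detector gain, in [50, 100].
#' @slot corrected logical; \code{TRUE} after background subtraction.
#' @slot nClipped number of points clipped to zero during subtraction.
#' @exportClass KineticTrace
setClass("KineticTrace",
  representation(
    wellId = "character", time = "numeric", od600 = "numeric",
    fluorescence = "numeric", gain = "numeric",
    corrected = "logical", nClipped = "integer"
  ),
  prototype(corrected = FALSE, nClipped = 0L)
)

setValidity("KineticTrace", function(object) {
  msgs <- character()
  nt <- length(object@time)
  if (length(object@od600) != nt || length(object@fluorescence) != nt)
    msgs <- c(msgs, "time, od600 and fluorescence must have equal lengths")
  if (nt > 1L && any(diff(object@time) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (length(object@gain) != 1L || is.na(object@gain) ||
      object@gain < 50 || object@gain > 100)
    msgs <- c(msgs, "gain must be a single value in [50, 100]")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn KineticTrace-class constructor.
#' @param wellId,time,od600,fluorescence,gain see slots.
#' @export
kineticTrace <- function(wellId, time, od600, fluorescence, gain) {
  new("KineticTrace",
    wellId = as.character(wellId), time = as.numeric(time),
    od600 = as.numeric(od600), fluorescence = as.numeric(fluorescence),
    gain = as.numeric(gain)
  )
}

setMethod("show", "KineticTrace", function(object) {
  cat(sprintf("KineticTrace '%s': %d points, %g-%g min, gain %g%s\n",
    object@wellId, length(object@time),
    if (length(object@time)) min(object@time) else NA,
    if (length(object@time)) max(object@time) else NA,
    object@gain,
    if (object@corrected) sprintf(", background-corrected (%d clipped)",
                                  object@nClipped) else ""))
  invisible(NULL)
})

#' Microplate kinetic data container
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] subclass holding a
#' whole plate: rows are wells, columns are acquisition timepoints. Assays
#' \code{od600} and \code{fluorescence} carry the raw readings; \code{rowData}
#' carries per-well metadata (\code{well_id}, \code{device}, \code{condition},
#' \code{dose_nM}, \code{clone}, \code{gain}); \code{colData$time_min} carries
#' the shared acquisition grid.
#'
#' @exportClass PlateKinetics
setClass("PlateKinetics", contains = "SummarizedExperiment")

setValidity("PlateKinetics", function(object) {
  msgs <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("od600", "fluorescence") %in% an))
    msgs <- c(msgs, "assays 'od600' and 'fluorescence' are required")
  cd <- SummarizedExperiment::colData(object)
  if (!"time_min" %in% colnames(cd)) {
    msgs <- c(msgs, "colData must contain 'time_min'")
  } else if (ncol(object) > 1L && any(diff(cd$time_min) <= 0)) {
    msgs <- c(msgs, "colData$time_min must be strictly increasing")
  }
  rd <- SummarizedExperiment::rowData(object)
  need <- c("well_id", "device", "condition", "dose_nM", "clone", "gain")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msgs <- c(msgs, paste0("rowData lacks column(s): ",
                           paste(miss, collapse = ", ")))
  if ("gain" %in% colnames(rd) && nrow(rd) &&
      any(rd$gain < 50 | rd$gain > 100, na.rm = TRUE))
    msgs <- c(msgs, "well gains must lie in [50, 100]")
  if (length(msgs)) msgs else TRUE
})

#' Build a PlateKinetics object
#'
#' @param od600,fluorescence numeric matrices, wells x timepoints.
#' @param time acquisition times (min), one per column.
#' @param wellData a \code{data.frame} or \code{DataFrame} with one row per
#'   well and columns \code{well_id}, \code{device}, \code{condition},
#'   \code{dose_nM}, \code{clone}, \code{gain}.
#' @return A [PlateKinetics-class] object.
#' @export
plateKinetics <- function(od600, fluorescence, time, wellData) {
  od600 <- as.matrix(od600); fluorescence <- as.matrix(fluorescence)
  wellData <- S4Vectors::DataFrame(wellData)
  rownames(od600) <- rownames(fluorescence) <- wellData$well_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(od600 = od600, fluorescence = fluorescence),
    rowData = wellData,
    colData = S4Vectors::DataFrame(time_min = as.numeric(time))
  )
  new("PlateKinetics", se)
}

setMethod("show", "PlateKinetics", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat(sprintf("PlateKinetics: %d wells x %d timepoints\n",
              nrow(object), ncol(object)))
  cat(sprintf("  devices: %s\n",
              paste(sort(unique(rd$device)), collapse = ", ")))
  tm <- SummarizedExperiment::colData(object)$time_min
  if (length(tm))
    cat(sprintf("  time: %g-%g min (interval %g min)\n",
                min(tm), max(tm), if (length(tm) > 1) tm[2] - tm[1] else NA))
  invisible(NULL)
})

#' Exponential-phase growth estimate
#'
#' @slot windowStart,windowEnd indices (into the trace) of the detected
#'   exponential window.
#' @slot rate slope m of the ln(OD600) regression (min\eqn{^{-1}}).
#' @slot doublingTime ln(2)/m (min).
#' @slot r2 coefficient of determination of the ln(OD) linear fit.
#' @exportClass GrowthEstimate
setClass("GrowthEstimate",
  representation(windowStart = "integer", windowEnd = "integer",
                 rate = "numeric", doublingTime = "numeric", r2 = "numeric")
)

setValidity("GrowthEstimate", function(object) {
  msgs <- character()
  if (object@windowEnd - object@windowStart + 1L < 5L)
    msgs <- c(msgs, "exponential window must span at least 5 points")
  if (!is.finite(object@rate) || object@rate <= 0)
    msgs <- c(msgs, "growth rate must be positive")
  if (abs(object@doublingTime - log(2) / object@rate) >
      1e-8 * object@doublingTime)
    msgs <- c(msgs, "doublingTime must equal ln(2)/rate")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GrowthEstimate", function(object) {
  cat(sprintf(
    "GrowthEstimate: m = %.5g /min, doubling time = %.4g min, R2 = %.4f, window [%d, %d]\n",
    object@rate, object@doublingTime, object@r2,
    object@windowStart, object@windowEnd))
  invisible(NULL)
})

#' @describeIn GrowthEstimate-class growth rate m (min^-1).
#' @param x a \code{GrowthEstimate}.
#' @export
growthRate <- function(x) x@rate

#' @describeIn GrowthEstimate-class doubling time ln(2)/m (min).
#' @export
doublingTime <- function(x) x@doublingTime

#' Per-cell reporter synthesis rate estimate
#'
#' The S_cell statistic: time derivative of background-corrected fluorescence
#' divided by OD600, averaged over the exponential phase (starting at least
#' 50 min after induction when an induction time is given), normalized to
#' detector gain 50.
#'
#' @slot value S_cell in AU min\eqn{^{-1}} cell\eqn{^{-1}} at gain 50.
#' @slot windowStart,windowEnd averaging window bounds in minutes.
#' @slot nPoints number of points averaged.
#' @slot gain the gain the trace was acquired at (before normalization).
#' @exportClass SCellEstimate
setClass("SCellEstimate",
  representation(value = "numeric", windowStart = "numeric",
                 windowEnd = "numeric", nPoints = "integer", gain = "numeric")
)

setMethod("show", "SCellEstimate", function(object) {
  cat(sprintf(
    "SCellEstimate: %.5g AU/min/cell at gain 50 (%d points, %g-%g min, acquired at gain %g)\n",
    object@value, object@nPoints, object@windowStart, object@windowEnd,
    object@gain))
  invisible(NULL)
})

#' @describeIn SCellEstimate-class numeric S_cell value at gain 50.
#' @param x an \code{SCellEstimate}.
#' @export
scellValue <- function(x) if (is(x, "SCellEstimate")) x@value else as.numeric(x)

#' Detector gain calibration
#'
#' Maps each gain to its conversion factor relative to gain 50 (the
#' RFP_norm,50 calibration curve). Factor at gain 50 is exactly 1.
#'
#' @slot gains gains measured.
#' @slot factors conversion factors (reading at gain / reading at gain 50).
#' @slot monotone logical; \code{FALSE} when the fitted factors were not
#'   strictly increasing in gain (kept, flagged).
#' @exportClass GainCalibration
setClass("GainCalibration",
  representation(gains = "numeric", factors = "numeric", monotone = "logical")
)

setValidity("GainCalibration", function(object) {
  msgs <- character()
  if (length(object@gains) != length(object@factors))
    msgs <- c(msgs, "gains and factors must have equal length")
  if (!50 %in% object@gains) {
    msgs <- c(msgs, "calibration must include gain 50")
  } else if (abs(object@factors[match(50, object@gains)] - 1) > 1e-12) {
    msgs <- c(msgs, "factor at gain 50 must be exactly 1")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GainCalibration", function(object) {
  cat("GainCalibration (relative to gain 50):\n")
  print(setNames(signif(object@factors, 4), object@gains))
  if (!object@monotone) cat("  WARNING: factors are not strictly increasing\n")
  invisible(NULL)
})

#' Hill dose-response fit result
#'
#' Parameters of Y = Vmax * I^q / (Km^q + I^q) with per-parameter coefficients
#' of variation (asymptotic standard error / estimate, in percent).
#'
#' @slot vmax maximum response.
#' @slot km half-saturation input level.
#' @slot q Hill exponent.
#' @slot cv named numeric, CV% for \code{vmax}, \code{km}, \code{q} (NA for a
#'   fixed parameter).
#' @slot rss residual sum of squares at the optimum.
#' @slot converged logical.
#' @slot vmaxFixed logical; \code{TRUE} when Vmax was supplied, not fitted.
#' @slot cvReliable logical; \code{FALSE} when the Jacobian was
#'   ill-conditioned at the optimum.
#' @slot nPoints number of points fitted.
#' @exportClass HillFit
setClass("HillFit",
  representation(vmax = "numeric", km = "numeric", q = "numeric",
                 cv = "numeric", rss = "numeric", converged = "logical",
                 vmaxFixed = "logical", cvReliable = "logical",
                 nPoints = "integer")
)

setValidity("HillFit", function(object) {
  msgs <- c(
    .checkPositiveScalar(object@vmax, "vmax"),
    .checkPositiveScalar(object@km, "km"),
    .checkPositiveScalar(object@q, "q")
  )
  if (any(object@cv < 0, na.rm = TRUE))
    msgs <- c(msgs, "CVs must be non-negative")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "HillFit", function(object) {
  fmt <- function(v, cv) {
    if (is.na(cv)) sprintf("%.4g (fixed)", v) else sprintf("%.4g (%.3g%%)", v, cv)
  }
  cat("HillFit: Y = Vmax * I^q / (Km^q + I^q)\n")
  cat(sprintf("  Vmax = %s\n", fmt(object@vmax, object@cv[["vmax"]])))
  cat(sprintf("  Km   = %s\n", fmt(object@km, object@cv[["km"]])))
  cat(sprintf("  q    = %s\n", fmt(object@q, object@cv[["q"]])))
  cat(sprintf("  RSS = %.4g on %d points; converged: %s%s\n",
              object@rss, object@nPoints, object@converged,
              if (!object@cvReliable) "; CVs flagged unreliable" else ""))
  invisible(NULL)
})

#' Per-condition transfer-function estimate on the activated-complex axis
#'
#' @slot condition copy-number condition label (SC/LC/MC/HC).
#' @slot vmax full-induction RPU (carried over from the HSL-axis Hill fit).
#' @slot kA dissociation constant of complex-promoter (AU cell^-1).
#' @slot nA Hill cooperativity of complex-promoter.
#' @slot alphaLux maximum per-copy reporter synthesis rate, Vmax * S_cell_ref / n.
#' @slot cv named CV% for kA and nA.
#' @slot n unrounded mean copy number used for the axis transform.
#' @slot scellRef reference-device S_cell used for alphaLux.
#' @exportClass ConditionEstimate
setClass("ConditionEstimate",
  representation(condition = "character", vmax = "numeric", kA = "numeric",
                 nA = "numeric", alphaLux = "numeric", cv = "numeric",
                 n = "numeric", scellRef = "numeric")
)

setValidity("ConditionEstimate", function(object) {
  msgs <- c(
    .checkPositiveScalar(object@vmax, "vmax"),
    .checkPositiveScalar(object@kA, "kA"),
    .checkPositiveScalar(object@nA, "nA"),
    .checkPositiveScalar(object@alphaLux, "alphaLux", allowNA = TRUE),
    .checkPositiveScalar(object@n, "n", allowNA = TRUE),
    .checkPositiveScalar(object@scellRef, "scellRef", allowNA = TRUE)
  )
  ok <- !is.na(object@alphaLux) && !is.na(object@n) && !is.na(object@scellRef)
  if (ok && abs(object@alphaLux - object@vmax * object@scellRef / object@n) >
      1e-6 * object@alphaLux)
    msgs <- c(msgs, "alphaLux must equal vmax * scellRef / n")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ConditionEstimate", function(object) {
  cat(sprintf(
    "ConditionEstimate [%s]: Vmax = %.4g RPU, K_A = %.4g (%.3g%%), n_A = %.4g (%.3g%%), alpha_lux = %.4g (n = %.4g)\n",
    object@condition, object@vmax, object@kA, object@cv[["kA"]],
    object@nA, object@cv[["nA"]], object@alphaLux, object@n))
  invisible(NULL)
})
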