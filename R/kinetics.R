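#' Extract one well's trace from a plate
#'
#' @param x a [PlateKinetics-class].
#' @param wellId well identifier (rowData \code{well_id}).
#' @return A [KineticTrace-class].
#' @export
wellTrace <- function(x, wellId) {
  stopifnot(is(x, "PlateKinetics"))
  rd <- SummarizedExperiment::rowData(x)
  i <- match(wellId, rd$well_id)
  if (is.na(i)) stop(sprintf("well '%s' not found", wellId))
  kineticTrace(
    wellId = wellId,
    time = SummarizedExperiment::colData(x)$time_min,
    od600 = SummarizedExperiment::assay(x, "od600")[i, ],
    fluorescence = SummarizedExperiment::assay(x, "fluorescence")[i, ],
    gain = rd$gain[i]
  )
}

# Align a background trace onto `times`. Exact grid match passes through;
# mismatches up to half the sampling interval are resolved by linear
# interpolation; anything worse is an alignment error.
.alignSeries <- function(times, bgTimes, bgValues, what) {
  if (length(bgTimes) == length(times) &&
      isTRUE(all.equal(bgTimes, times, tolerance = 1e-9)))
    return(bgValues)
  step <- if (length(times) > 1L) min(diff(times)) else Inf
  if (min(bgTimes) > min(times) + step / 2 ||
      max(bgTimes) < max(times) - step / 2)
    stop(sprintf("alignment error: %s trace does not cover the target time grid",
                 what))
  nearest <- vapply(times, function(tt) min(abs(bgTimes - tt)), numeric(1L))
  if (any(nearest > step / 2))
    stop(sprintf(
      "alignment error: %s grid offset (%.3g min) exceeds half the sampling interval",
      what, max(nearest)))
  approx(bgTimes, bgValues, xout = times, rule = 2)$y
}

#' Subtract background time series from a raw trace
#'
#' OD600 is corrected by subtracting the medium-blank absorbance time series;
#' fluorescence by subtracting the non-fluorescent-strain time series, which
#' captures both medium fluorescence and cell autofluorescence. When the
#' background well was acquired at a different gain, its fluorescence is first
#' rescaled to the trace's gain through the calibration curve (detector gain
#' scales background and signal alike).
#'
#' Negative corrected values are clipped to 0 and counted in the returned
#' trace's \code{nClipped} slot: downstream ratio operations need
#' non-negativity, and a large count flags pathological inputs.
#'
#' @param trace raw [KineticTrace-class] of the culture of interest.
#' @param blank [KineticTrace-class] of the medium blank (absorbance
#'   background).
#' @param nonfluo [KineticTrace-class] of the non-fluorescent strain
#'   (fluorescence background).
#' @param calibration optional [GainCalibration-class]; required when
#'   \code{nonfluo} and \code{trace} gains differ.
#' @return A corrected [KineticTrace-class] (\code{corrected = TRUE}).
#' @export
subtractBackgrounds <- function(trace, blank, nonfluo, calibration = NULL) {
  stopifnot(is(trace, "KineticTrace"), is(blank, "KineticTrace"),
            is(nonfluo, "KineticTrace"))
  bgOD <- .alignSeries(trace@time, blank@time, blank@od600, "blank OD")
  bgFl <- .alignSeries(trace@time, nonfluo@time, nonfluo@fluorescence,
                       "non-fluorescent-strain")
  if (nonfluo@gain != trace@gain) {
    if (is.null(calibration))
      stop("calibration error: background gain differs from trace gain and no calibration was supplied")
    bgFl <- bgFl * calibrationFactor(calibration, trace@gain) /
      calibrationFactor(calibration, nonfluo@gain)
  }
  od <- trace@od600 - bgOD
  fl <- trace@fluorescence - bgFl
  nClip <- sum(od < 0) + sum(fl < 0)
  out <- kineticTrace(trace@wellId, trace@time, pmax(od, 0), pmax(fl, 0),
                      trace@gain)
  out@corrected <- TRUE
  out@nClipped <- as.integer(nClip)
  out
}

# Sliding-window ln(OD) linear regressions in O(1) per window via cumsums.
.windowRegression <- function(x, y) {
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x * x); cxy <- cumsum(x * y); cyy <- cumsum(y * y)
  at <- function(v, i) if (i < 1L) 0 else v[i]
  function(i, j) {
    n <- j - i + 1L
    sx <- cx[j] - at(cx, i - 1L); sy <- cy[j] - at(cy, i - 1L)
    sxx <- cxx[j] - at(cxx, i - 1L); sxy <- cxy[j] - at(cxy, i - 1L)
    syy <- cyy[j] - at(cyy, i - 1L)
    ssx <- sxx - sx * sx / n
    ssy <- syy - sy * sy / n
    sxyc <- sxy - sx * sy / n
    slope <- sxyc / ssx
    r2 <- if (ssy <= 0) NA_real_ else (sxyc * sxyc) / (ssx * ssy)
    c(slope = slope, r2 = r2)
  }
}

#' Detect the exponential growth phase
#'
#' Automated analogue of identifying the linear region of the ln(OD600) time
#' series by eye: among all sliding windows of at least \code{minLength}
#' points whose OD lies between \code{floor} and \code{capFraction} times the
#' trace's OD maximum (a carrying-capacity estimate), the longest window with
#' ln(OD) linear-fit \eqn{R^2 \ge} \code{r2Threshold} and positive slope is
#' selected; ties are broken by higher \eqn{R^2}. The slope m of the least
#' squares line gives the growth rate and the doubling time ln(2)/m.
#'
#' @param trace a background-corrected [KineticTrace-class].
#' @param floor minimum OD considered reliable (default 0.01).
#' @param minLength minimum window length in points (default 6).
#' @param r2Threshold minimum \eqn{R^2} (default 0.99).
#' @param capFraction upper OD bound as a fraction of max OD (default 0.6).
#' @return A [GrowthEstimate-class].
#' @export
detectExponentialPhase <- function(trace, floor = 0.01, minLength = 6L,
                                   r2Threshold = 0.99, capFraction = 0.6) {
  stopifnot(is(trace, "KineticTrace"))
  od <- trace@od600
  eligible <- which(od >= floor & od <= capFraction * max(od))
  if (length(eligible) < 10L)
    stop(sprintf(
      "detection error: only %d points with OD in [%g, %g]; need >= 10",
      length(eligible), floor, capFraction * max(od)))
  y <- ifelse(od > 0, log(od), NA_real_)
  reg <- .windowRegression(trace@time, ifelse(is.na(y), 0, y))

  runs <- split(eligible, cumsum(c(1L, diff(eligible) != 1L)))
  best <- NULL; bestR2Seen <- -Inf
  for (run in runs) {
    L <- length(run)
    if (L < minLength) next
    for (i in seq_len(L - minLength + 1L)) {
      for (j in seq(i + minLength - 1L, L)) {
        st <- reg(run[i], run[j])
        if (!is.na(st[["r2"]])) bestR2Seen <- max(bestR2Seen, st[["r2"]])
        if (is.na(st[["r2"]]) || st[["r2"]] < r2Threshold ||
            st[["slope"]] <= 0) next
        len <- j - i + 1L
        if (is.null(best) || len > best$len ||
            (len == best$len && st[["r2"]] > best$r2)) {
          best <- list(i = run[i], j = run[j], len = len,
                       slope = st[["slope"]], r2 = st[["r2"]])
        }
      }
    }
  }
  if (is.null(best))
    stop(sprintf(
      "detection error: no window of >= %d points reached R2 >= %g (best R2 found: %.4f)",
      minLength, r2Threshold, bestR2Seen))

  # Endpoint trimming: the longest window passing the R2 gate can still
  # absorb a few lag or bend points (their residuals are small relative to
  # the window's full ln(OD) span). Greedily drop whichever endpoint
  # strictly improves R2 until no single drop helps, keeping >= minLength.
  i <- best$i; j <- best$j; cur <- reg(i, j)
  while (j - i + 1L > minLength) {
    dropFirst <- reg(i + 1L, j)
    dropLast <- reg(i, j - 1L)
    cand <- if (dropFirst[["r2"]] >= dropLast[["r2"]])
      list(i = i + 1L, j = j, st = dropFirst)
    else list(i = i, j = j - 1L, st = dropLast)
    if (is.na(cand$st[["r2"]]) || cand$st[["r2"]] <= cur[["r2"]]) break
    i <- cand$i; j <- cand$j; cur <- cand$st
  }
  if (cur[["slope"]] <= 0)
    stop("detection error: trimmed window has non-positive slope")
  new("GrowthEstimate",
    windowStart = as.integer(i), windowEnd = as.integer(j),
    rate = cur[["slope"]], doublingTime = log(2) / cur[["slope"]],
    r2 = cur[["r2"]])
}

# central differences interior, one-sided at the edges
.timeDerivative <- function(t, y) {
  n <- length(y)
  d <- numeric(n)
  if (n < 2L) return(d * NA_real_)
  d[1L] <- (y[2L] - y[1L]) / (t[2L] - t[1L])
  d[n] <- (y[n] - y[n - 1L]) / (t[n] - t[n - 1L])
  if (n > 2L) {
    i <- 2L:(n - 1L)
    d[i] <- (y[i + 1L] - y[i - 1L]) / (t[i + 1L] - t[i - 1L])
  }
  d
}

#' Estimate the per-cell reporter synthesis rate (S_cell)
#'
#' Computes the numeric time derivative of the background-corrected
#' fluorescence (central differences in the interior, one-sided at the
#' edges), divides it pointwise by the corrected OD600, and averages over the
#' intersection of the detected exponential window with times at least 50 min
#' after induction (when an induction time is supplied; otherwise the full
#' exponential window is used, the convention for constitutive wells). The
#' average is then divided by the calibration factor of the trace's gain to
#' report S_cell at gain 50.
#'
#' @param trace a background-corrected [KineticTrace-class].
#' @param growth the trace's [GrowthEstimate-class].
#' @param calibration a [GainCalibration-class] covering the trace's gain.
#' @param inductionTime induction time in minutes, or \code{NULL} for
#'   no induction-based exclusion.
#' @param postInductionDelay exclusion after induction (min), default 50.
#' @return An [SCellEstimate-class] (value at gain 50).
#' @export
estimateScell <- function(trace, growth, calibration, inductionTime = NULL,
                          postInductionDelay = 50) {
  stopifnot(is(trace, "KineticTrace"), is(growth, "GrowthEstimate"),
            is(calibration, "GainCalibration"))
  idx <- growth@windowStart:growth@windowEnd
  if (!is.null(inductionTime))
    idx <- idx[trace@time[idx] >= inductionTime + postInductionDelay]
  if (!length(idx))
    stop("window error: exponential window does not overlap the post-induction period")
  dF <- .timeDerivative(trace@time, trace@fluorescence)
  ratio <- dF[idx] / trace@od600[idx]
  ratio <- ratio[is.finite(ratio)]
  if (!length(ratio))
    stop("window error: no finite derivative/OD points in the averaging window")
  value <- mean(ratio) / calibrationFactor(calibration, trace@gain)
  new("SCellEstimate",
    value = value,
    windowStart = trace@time[idx[1L]], windowEnd = trace@time[idx[length(idx)]],
    nPoints = length(ratio), gain = trace@gain)
}

#' Fit the gain calibration curve
#'
#' Divides every calibration reading by the reading at gain 50, yielding the
#' conversion factor (RFP_norm,50) for each gain. Factors are expected to be
#' strictly increasing in gain; a violation is kept but flagged with a
#' warning, since downstream normalization only needs the ratios.
#'
#' @param series data.frame with columns \code{gain} and \code{reading}, as
#'   produced by [simulateCalibrationSeries()] or read from an export.
#' @return A [GainCalibration-class].
#' @export
fitGainCalibration <- function(series) {
  stopifnot(is.data.frame(series), all(c("gain", "reading") %in% names(series)))
  if (!50 %in% series$gain)
    stop("calibration error: series lacks the gain-50 anchor")
  o <- order(series$gain)
  gains <- series$gain[o]
  factors <- series$reading[o] / series$reading[o][gains == 50]
  monotone <- all(diff(factors) > 0)
  if (!monotone)
    warning("calibration factors are not strictly increasing in gain; kept, flagged")
  new("GainCalibration", gains = gains, factors = factors,
      monotone = monotone)
}

#' Conversion factor for a gain
#'
#' Looks up (or log-linearly interpolates within the measured range) the
#' calibration factor for \code{gain}. Gains outside the calibrated range are
#' a calibration error.
#'
#' @param calibration a [GainCalibration-class].
#' @param gain gain to convert.
#' @return Numeric factor relative to gain 50.
#' @export
calibrationFactor <- function(calibration, gain) {
  stopifnot(is(calibration, "GainCalibration"))
  i <- match(gain, calibration@gains)
  if (!is.na(i)) return(calibration@factors[i])
  if (gain < min(calibration@gains) || gain > max(calibration@gains))
    stop(sprintf("calibration error: gain %g outside calibrated range [%g, %g]",
                 gain, min(calibration@gains), max(calibration@gains)))
  exp(approx(calibration@gains, log(calibration@factors), xout = gain)$y)
}

#' Process every measurement well of a plate
#'
#' Convenience wrapper chaining background subtraction, exponential-phase
#' detection and S_cell estimation for all non-control wells.
#'
#' @param kinetics a [PlateKinetics-class] containing wells labelled
#'   \code{blank} and \code{nonfluo} among its rows.
#' @param calibration a [GainCalibration-class].
#' @param inductionTime passed to [estimateScell()] for inducible wells; also
#'   applied to constitutive wells (uniform-exclusion convention) unless
#'   \code{NULL}.
#' @return data.frame with one row per measurement well: metadata columns
#'   plus \code{m}, \code{doubling_time_min}, \code{r2}, \code{scell_gain50},
#'   \code{window_start_min}, \code{window_end_min}, \code{n_clipped}.
#' @export
processPlate <- function(kinetics, calibration, inductionTime = 0) {
  stopifnot(is(kinetics, "PlateKinetics"))
  rd <- as.data.frame(SummarizedExperiment::rowData(kinetics))
  blankId <- rd$well_id[rd$device == "blank"]
  nfId <- rd$well_id[rd$device == "nonfluo"]
  if (length(blankId) != 1L || length(nfId) != 1L)
    stop("plate must contain exactly one 'blank' and one 'nonfluo' well")
  blank <- wellTrace(kinetics, blankId)
  nonfluo <- wellTrace(kinetics, nfId)
  meas <- rd[!rd$device %in% c("blank", "nonfluo"), , drop = FALSE]
  res <- lapply(meas$well_id, function(id) {
    tr <- subtractBackgrounds(wellTrace(kinetics, id), blank, nonfluo,
                              calibration)
    gr <- detectExponentialPhase(tr)
    sc <- estimateScell(tr, gr, calibration, inductionTime = inductionTime)
    data.frame(well_id = id, m = gr@rate, doubling_time_min = gr@doublingTime,
               r2 = gr@r2, scell_gain50 = sc@value,
               window_start_min = sc@windowStart,
               window_end_min = sc@windowEnd, n_clipped = tr@nClipped,
               stringsAsFactors = FALSE)
  })
  merge(meas, do.call(rbind, res), by = "well_id", sort = FALSE)
}
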