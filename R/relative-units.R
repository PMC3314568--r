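#' Relative promoter units
#'
#' RPU of a device: its S_cell divided by the S_cell of the reference device
#' (101_RFP, carrying the J23101 standard promoter) measured in the same
#' copy-number condition and reported at the same gain. Both inputs must be
#' gain-50 normalized (the [estimateScell()] output always is), which makes
#' "same gain" automatic.
#'
#' @param scellX S_cell of the device of interest: an [SCellEstimate-class]
#'   or a numeric value at gain 50.
#' @param scellRef S_cell of the reference device, likewise.
#' @param condition,conditionRef optional condition labels; supplied labels
#'   must match (pairing error otherwise).
#' @return Numeric RPU.
#' @examples
#' rpu(0.54, 0.69)  # lacIQ vs J23101 at single copy: 0.783
#' @export
rpu <- function(scellX, scellRef, condition = NULL, conditionRef = NULL) {
  x <- scellValue(scellX); ref <- scellValue(scellRef)
  if (!is.null(condition) && !is.null(conditionRef) &&
      !identical(condition, conditionRef))
    stop(sprintf("pairing error: condition '%s' does not match reference condition '%s'",
                 condition, conditionRef))
  if (is.na(ref) || ref <= 0)
    stop("reference error: reference S_cell must be positive")
  x / ref
}

#' Indirect DNA copy-number estimate from constitutive S_cell
#'
#' Divides each condition's S_cell by the single-copy (SC) value of the same
#' device, giving a rough, indirect copy-number estimate (SC is 1 by
#' definition). The unrounded ratio is reported alongside the
#' nearest-integer estimate: downstream model work consumes the unrounded
#' values, the integers are the conventional presentation.
#'
#' @param scellByCondition named numeric of S_cell per condition; must
#'   include \code{"SC"}.
#' @return data.frame with columns \code{condition}, \code{ratio}
#'   (unrounded), \code{estimate} (nearest integer).
#' @examples
#' copyNumberEstimate(c(SC = 0.69, LC = 2.48, MC = 34.2, HC = 88.36))
#' @export
copyNumberEstimate <- function(scellByCondition) {
  if (!"SC" %in% names(scellByCondition))
    stop("baseline error: single-copy (SC) entry is required")
  base <- scellByCondition[["SC"]]
  if (is.na(base) || base <= 0)
    stop("baseline error: SC S_cell must be positive")
  ratio <- unname(scellByCondition) / base
  data.frame(condition = names(scellByCondition), ratio = ratio,
             estimate = round(ratio), stringsAsFactors = FALSE)
}

#' Mean copy number across constitutive devices
#'
#' Arithmetic mean, per condition, of the unrounded copy-number ratios of the
#' available constitutive devices. This unrounded mean is the copy number the
#' model-based axis transform uses.
#'
#' @param estimates data.frame with columns \code{device}, \code{condition},
#'   \code{ratio} (stack the outputs of [copyNumberEstimate()] per device),
#'   or a list of such data.frames.
#' @return Named numeric: mean unrounded ratio per condition.
#' @examples
#' sc <- referenceScell()
#' est <- do.call(rbind, lapply(split(sc, sc$device), function(d) {
#'   cbind(device = d$device[1], copyNumberEstimate(setNames(d$scell, d$condition)))
#' }))
#' meanCopyNumber(est)["HC"]  # 118.75
#' @export
meanCopyNumber <- function(estimates) {
  if (is.list(estimates) && !is.data.frame(estimates))
    estimates <- do.call(rbind, estimates)
  if (!is.data.frame(estimates) || !nrow(estimates))
    stop("empty input: no copy-number estimates supplied")
  stopifnot(all(c("condition", "ratio") %in% names(estimates)))
  vapply(split(estimates$ratio, estimates$condition), mean, numeric(1L))
}

#' Scar-corrected RPU
#'
#' The assembly scar between promoter and RBS differs between the measured
#' device and the reference device; the measured scar variant overestimates
#' promoter activity by a fixed factor (1.43 in this characterization).
#' Dividing by the scar factor converts to the reference-scar convention.
#' The correction is exposed but not applied by default anywhere in the
#' pipeline.
#'
#' @param rpuValue numeric RPU value(s).
#' @param scarFactor positive correction factor, default 1.43.
#' @return Corrected RPU value(s).
#' @export
scarCorrectedRpu <- function(rpuValue, scarFactor = 1.43) {
  if (is.na(scarFactor) || scarFactor <= 0)
    stop("scarFactor must be positive")
  rpuValue / scarFactor
}

#' Summarize per-clone values into a mean and 95% confidence interval
#'
#' Student-t confidence interval of the mean with clone-level values as the
#' units (the conventional reading of "95% confidence intervals computed on
#' 3 clones").
#'
#' @param values numeric vector of per-clone values (RPU or S_cell), length
#'   at least 2.
#' @return list with \code{mean}, \code{ci95} (half-width), \code{n}.
#' @export
summarizeCondition <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L)
    stop("summary error: at least 2 clones are required for a confidence interval")
  m <- mean(values)
  half <- qt(0.975, df = n - 1L) * sd(values) / sqrt(n)
  list(mean = m, ci95 = half, n = n)
}
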