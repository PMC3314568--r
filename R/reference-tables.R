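#' Published characterization values used as simulation inputs
#'
#' These tables carry the published characterization of the device family that
#' this package's synthetic generator emulates and that desk-scale checks
#' recompute from: per-cell synthesis rates of the constitutive reference
#' devices, culture doubling times, and the fitted transfer-function
#' parameters of the HSL-inducible device per copy-number condition. They are
#' inputs to the pipeline (ground truth for the generator, operands for the
#' ratio/identity operations), not outputs of it.
#'
#' @return \code{referenceScell()}: data.frame with columns \code{device}
#'   (\code{"101_RFP"}, \code{"IQ_RFP"}), \code{condition} (SC/LC/MC/HC) and
#'   \code{scell} (AU min^-1 cell^-1 at gain 50).
#' @examples
#' referenceScell()
#' @name referenceTables
#' @export
referenceScell <- function() {
  data.frame(
    device = rep(c("101_RFP", "IQ_RFP"), each = 4L),
    condition = rep(c("SC", "LC", "MC", "HC"), 2L),
    scell = c(0.69, 2.48, 34.2, 88.36,
              0.54, 2.14, 22.7, 59.1),
    stringsAsFactors = FALSE
  )
}

#' @rdname referenceTables
#' @return \code{referenceDoublingTimes()}: data.frame with columns
#'   \code{device}, \code{condition}, \code{doubling_min} and \code{cv_pct}
#'   (percent coefficient of variation across clones/inductions).
#' @export
referenceDoublingTimes <- function() {
  data.frame(
    device = rep(c("HSL_RFP", "101_RFP", "IQ_RFP"), each = 4L),
    condition = rep(c("SC", "LC", "MC", "HC"), 3L),
    doubling_min = c(86, 131, 63, 127,
                     86, 104, 59, 106,
                     101, 92, 65, 102),
    cv_pct = c(5, 9, 7, 15,
               8, 9, 8, 11,
               17, 5, 6, 5),
    stringsAsFactors = FALSE
  )
}

#' @rdname referenceTables
#' @return \code{referenceHillEstimates()}: data.frame with one row per
#'   copy-number condition and columns \code{condition}, \code{vmax} (RPU),
#'   \code{vmax_cv_pct}, \code{kA} (AU cell^-1), \code{kA_cv_pct}, \code{nA},
#'   \code{nA_cv_pct}, \code{alpha_lux} (AU min^-1 cell^-1) -- the fitted
#'   activated-complex transfer function per condition.
#' @export
referenceHillEstimates <- function() {
  data.frame(
    condition = c("SC", "LC", "MC", "HC"),
    vmax = c(8.79, 8.68, 5.00, 2.84),
    vmax_cv_pct = c(1, 2, 1, 2),
    kA = c(5.13e-4, 8.83e-4, 2.87e-3, 3.24e-2),
    kA_cv_pct = c(6, 22, 13, 18),
    nA = c(0.747, 0.437, 0.502, 0.504),
    nA_cv_pct = c(4, 8, 6, 8),
    alpha_lux = c(6.07, 5.70, 3.73, 2.11),
    stringsAsFactors = FALSE
  )
}

#' @rdname referenceTables
#' @return \code{referenceCopyNumbers()}: named numeric of unrounded mean
#'   copy-number estimates per condition, the arithmetic mean across the two
#'   constitutive devices of S_cell(condition)/S_cell(SC) computed from
#'   \code{referenceScell()}. SC is 1 by definition.
#' @export
referenceCopyNumbers <- function() {
  sc <- referenceScell()
  est <- lapply(split(sc, sc$device), function(d) {
    setNames(d$scell / d$scell[d$condition == "SC"], d$condition)
  })
  conds <- c("SC", "LC", "MC", "HC")
  vapply(conds, function(cc) {
    mean(vapply(est, `[[`, numeric(1L), cc))
  }, numeric(1L))
}
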