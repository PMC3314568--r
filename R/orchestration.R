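#' Write / read plate kinetics in the pinned CSV dialect
#'
#' Long format with columns \code{well_id}, \code{time_min},
#' \code{od600_raw}, \code{fluo_raw}, \code{gain}. Well metadata beyond the
#' gain travels separately (a design or a well table), matching how plate
#' readers export kinetics.
#'
#' @param x a [PlateKinetics-class].
#' @param path CSV file path.
#' @return \code{writePlateKinetics}: \code{path}, invisibly.
#' @export
writePlateKinetics <- function(x, path) {
  stopifnot(is(x, "PlateKinetics"))
  rd <- SummarizedExperiment::rowData(x)
  tm <- SummarizedExperiment::colData(x)$time_min
  long <- data.frame(
    well_id = rep(rd$well_id, each = length(tm)),
    time_min = rep(tm, times = nrow(x)),
    od600_raw = as.vector(t(SummarizedExperiment::assay(x, "od600"))),
    fluo_raw = as.vector(t(SummarizedExperiment::assay(x, "fluorescence"))),
    gain = rep(rd$gain, each = length(tm))
  )
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePlateKinetics
#' @param wellData optional data.frame with per-well metadata columns
#'   \code{well_id}, \code{device}, \code{condition}, \code{dose_nM},
#'   \code{clone}; defaults are filled with NA when absent.
#' @return \code{readPlateKinetics}: a [PlateKinetics-class].
#' @export
readPlateKinetics <- function(path, wellData = NULL) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "time_min", "od600_raw", "fluo_raw", "gain")
  miss <- setdiff(need, names(long))
  if (length(miss))
    stop(paste0("plate CSV lacks column(s): ", paste(miss, collapse = ", ")))
  wells <- unique(long$well_id)
  tm <- sort(unique(long$time_min))
  shape <- function(col) {
    m <- matrix(NA_real_, length(wells), length(tm),
                dimnames = list(wells, NULL))
    idx <- cbind(match(long$well_id, wells), match(long$time_min, tm))
    m[idx] <- long[[col]]
    m
  }
  gains <- vapply(wells, function(wl) long$gain[long$well_id == wl][1L],
                  numeric(1L))
  wd <- data.frame(well_id = wells, device = NA_character_,
                   condition = NA_character_, dose_nM = NA_real_,
                   clone = NA_integer_, gain = gains,
                   stringsAsFactors = FALSE)
  if (!is.null(wellData)) {
    keep <- setdiff(intersect(names(wd), names(wellData)), "well_id")
    i <- match(wd$well_id, wellData$well_id)
    for (cc in keep) wd[[cc]] <- wellData[[cc]][i]
    if (!"gain" %in% names(wellData)) wd$gain <- gains
  }
  plateKinetics(shape("od600_raw"), shape("fluo_raw"), tm, wd)
}

#' Validate a plate kinetics export
#'
#' Schema and sanity checks, enumerated rather than thrown one at a time:
#' required columns, strictly increasing times per well, gains in [50, 100],
#' and presence of the blank and non-fluorescent control wells (when device
#' labels are available). Never mutates its input.
#'
#' @param x a CSV path, a long-format data.frame, or a
#'   [PlateKinetics-class].
#' @param wellData optional metadata (see [readPlateKinetics()]) used to
#'   check for control wells when \code{x} has no device labels.
#' @return data.frame of violations with columns \code{code} and
#'   \code{message}; zero rows when the input is clean.
#' @export
validatePlateKinetics <- function(x, wellData = NULL) {
  viol <- function(code, message) data.frame(code = code, message = message,
                                             stringsAsFactors = FALSE)
  out <- list()
  if (is.character(x)) {
    if (!file.exists(x)) return(viol("missing_file", sprintf("no file at '%s'", x)))
    x <- read.csv(x, stringsAsFactors = FALSE)
  }
  if (is.data.frame(x)) {
    need <- c("well_id", "time_min", "od600_raw", "fluo_raw", "gain")
    miss <- setdiff(need, names(x))
    if (length(miss))
      return(viol("schema", paste0("missing column(s): ",
                                   paste(miss, collapse = ", "))))
    for (wl in unique(x$well_id)) {
      tt <- x$time_min[x$well_id == wl]
      if (any(diff(tt) <= 0))
        out[[length(out) + 1L]] <-
          viol("time_monotonicity",
               sprintf("well '%s': times not strictly increasing", wl))
    }
    gains <- x$gain
    devices <- if (!is.null(wellData)) wellData$device else NULL
  } else if (is(x, "PlateKinetics")) {
    rd <- SummarizedExperiment::rowData(x)
    gains <- rd$gain
    devices <- rd$device
    tm <- SummarizedExperiment::colData(x)$time_min
    if (any(diff(tm) <= 0))
      out[[length(out) + 1L]] <-
        viol("time_monotonicity", "times not strictly increasing")
  } else {
    return(viol("input_type", "unsupported input type"))
  }
  if (any(gains < 50 | gains > 100, na.rm = TRUE))
    out[[length(out) + 1L]] <- viol("gain_range", "gain(s) outside [50, 100]")
  if (!is.null(devices) && !all(is.na(devices))) {
    if (sum(devices == "blank", na.rm = TRUE) != 1L)
      out[[length(out) + 1L]] <-
        viol("missing_blank", "exactly one medium-blank well is required")
    if (sum(devices == "nonfluo", na.rm = TRUE) != 1L)
      out[[length(out) + 1L]] <-
        viol("missing_nonfluo",
             "exactly one non-fluorescent-strain well is required")
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(code = character(), message = character(),
               stringsAsFactors = FALSE)
}

#' Default pipeline configuration
#'
#' Single source of truth for the model constants and pipeline options. The
#' structure round-trips unchanged through JSON serialization
#' ([writeConfig()] / [readConfig()]).
#'
#' @return Nested list: \code{model} (the fixed constants), \code{pipeline}
#'   (R2 threshold, derivative method, post-induction delay, scar factor),
#'   \code{simulation} (dose grid, clones, noise defaults).
#' @export
defaultConfig <- function() {
  list(
    model = list(alpha_tet = 2.3, gamma_X = 6e-2, K_H = 553, n_H = 2),
    pipeline = list(r2_threshold = 0.99, min_window_points = 6,
                    od_floor = 0.01, cap_fraction = 0.6,
                    derivative = "central", post_induction_delay_min = 50,
                    scar_factor = 1.43),
    simulation = list(dose_grid_nM = c(0, 10^seq(log10(0.01), log10(1000),
                                                 length.out = 12)),
                      clones = 3, od_noise_sd = 0.002,
                      fluo_noise_sd_gain50 = 0.5, clone_sdlog = 0.05,
                      gain_slope = 0.02)
  )
}

#' @rdname defaultConfig
#' @param config a configuration list.
#' @param path JSON file path.
#' @export
writeConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname defaultConfig
#' @export
readConfig <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

.stage <- function(tag, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage: %s] %s", tag, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full characterization workflow on synthetic data
#'
#' The end-to-end emulation of the study: simulate a calibration series and a
#' characterization plate, process every well into growth and S_cell
#' estimates, compute RPUs against the 101_RFP reference per condition,
#' estimate copy numbers from the constitutive devices, fit the Hill
#' induction curve per condition on the HSL axis, transform the axis to the
#' activated complex and fit (K_A, n_A) with alpha_lux from the Vmax
#' identity, then summarize the K_A-vs-copy-number trend. Deterministic for a
#' fixed seed.
#'
#' @param seed integer seed driving the calibration and plate simulations.
#' @param design a [PlateDesign-class]; default the full
#'   [characterizationDesign()].
#' @param config configuration list, see [defaultConfig()].
#' @param sensitivity logical; also run the 2-fold alphaTet sensitivity grid.
#' @param assumedCopyNumbers optional named numeric of copy numbers per
#'   condition. Indirect copy-number estimation needs the single-copy (SC)
#'   anchor; a sub-plate analysis without SC wells must state the copy
#'   numbers to use for the axis transform.
#' @return list with elements \code{wells} (per-well results table),
#'   \code{scellTable} (device x condition means with 95% CI),
#'   \code{doublingTimeTable}, \code{copyNumbers} (per-device ratios and
#'   unrounded means), \code{lacIQ} (per-condition RPU summary and grand
#'   mean), \code{inductionCurves} (per-condition dose/RPU tables with A),
#'   \code{hillFits} (HSL-axis [HillFit-class] per condition),
#'   \code{conditionEstimates} ([ConditionEstimate-class] per condition),
#'   \code{estimatesTable} (Vmax / K_A / n_A / alpha_lux per condition),
#'   \code{trend}, and optionally \code{sensitivity}; plus \code{log}
#'   (seed, config, clipping and convergence counts).
#' @export
runCharacterization <- function(seed = 1L, design = characterizationDesign(),
                                config = defaultConfig(),
                                sensitivity = FALSE,
                                assumedCopyNumbers = NULL) {
  seed <- as.integer(seed)
  calib <- .stage("calibration", {
    noiseSd <- if (design@noiseFluo > 0)
      config$simulation$fluo_noise_sd_gain50 else 0
    fitGainCalibration(simulateCalibrationSeries(
      seed = seed, noiseSd = noiseSd, slope = design@gainSlope))
  })
  sim <- .stage("simulate", simulatePlate(design, seed = seed))
  wells <- .stage("process",
                  processPlate(sim$kinetics, calib,
                               inductionTime = design@inductionTime))

  summarize <- function(v) {
    if (length(v) >= 2L) summarizeCondition(v)
    else list(mean = mean(v), ci95 = NA_real_, n = length(v))
  }
  condLevels <- intersect(c("SC", "LC", "MC", "HC"),
                          unique(wells$condition))

  # device x condition S_cell and doubling-time summaries over clones
  isConst <- wells$device %in% c("101_RFP", "IQ_RFP")
  atFull <- wells$device == "HSL_RFP" &
    wells$dose_nM == max(wells$dose_nM[wells$device == "HSL_RFP"], -Inf)
  sel <- isConst | atFull
  scellTable <- do.call(rbind, lapply(
    split(wells[sel, ], list(wells$device[sel], wells$condition[sel]),
          drop = TRUE),
    function(d) {
      s <- summarize(d$scell_gain50)
      g <- summarize(d$doubling_time_min)
      data.frame(device = d$device[1L], condition = d$condition[1L],
                 scell = s$mean, scell_ci95 = s$ci95,
                 doubling_min = g$mean, doubling_ci95 = g$ci95,
                 clones = s$n, stringsAsFactors = FALSE)
    }))
  rownames(scellTable) <- NULL
  doublingTimeTable <- scellTable[, c("device", "condition", "doubling_min",
                                      "doubling_ci95", "clones")]

  scellOf <- function(dev, cond) {
    scellTable$scell[scellTable$device == dev & scellTable$condition == cond]
  }

  copyNumbers <- .stage("copy-number", {
    if (!"SC" %in% condLevels && !is.null(assumedCopyNumbers)) {
      list(perDevice = NULL,
           mean = vapply(condLevels, function(cc)
             assumedCopyNumbers[[cc]], numeric(1L)))
    } else {
      perDevice <- do.call(rbind, lapply(c("101_RFP", "IQ_RFP"),
                                         function(dev) {
        v <- setNames(vapply(condLevels, function(cc) scellOf(dev, cc),
                             numeric(1L)), condLevels)
        cbind(device = dev, copyNumberEstimate(v))
      }))
      list(perDevice = perDevice, mean = meanCopyNumber(perDevice))
    }
  })

  lacIQ <- .stage("rpu", {
    perCond <- vapply(condLevels, function(cc) {
      rpu(scellOf("IQ_RFP", cc), scellOf("101_RFP", cc), cc, cc)
    }, numeric(1L))
    list(perCondition = perCond, grandMean = mean(perCond),
         scarCorrected = scarCorrectedRpu(perCond,
                                          config$pipeline$scar_factor))
  })

  constants <- luxModelParameters(
    alphaTet = config$model$alpha_tet, gammaX = config$model$gamma_X,
    KH = config$model$K_H, nH = config$model$n_H)

  hsl <- wells[wells$device == "HSL_RFP", ]
  inductionCurves <- list(); hillFits <- list(); conditionEstimates <- list()
  for (cond in condLevels) {
    d <- hsl[hsl$condition == cond, ]
    if (!nrow(d)) next
    ref <- scellOf("101_RFP", cond)
    curve <- do.call(rbind, lapply(split(d, d$dose_nM), function(dd) {
      s <- summarize(dd$scell_gain50 / ref)
      data.frame(dose_nM = dd$dose_nM[1L], rpu = s$mean, rpu_ci95 = s$ci95,
                 clones = s$n, stringsAsFactors = FALSE)
    }))
    curve <- curve[order(curve$dose_nM), ]
    rownames(curve) <- NULL
    nCond <- copyNumbers$mean[[cond]]
    ax <- .stage("transform-axis",
                 transformAxis(curve$dose_nM, nCond, constants))
    curve$A <- ax$A
    inductionCurves[[cond]] <- curve
    hillFits[[cond]] <- .stage(paste0("fit-hill:", cond),
                               fitHill(curve$dose_nM, curve$rpu))
    conditionEstimates[[cond]] <- .stage(paste0("fit-complex:", cond),
      fitComplexCurve(curve$A, curve$rpu, vmax = hillFits[[cond]]@vmax,
                      condition = cond, n = nCond, scellRef = ref))
  }

  estimatesTable <- do.call(rbind, lapply(conditionEstimates, function(e) {
    data.frame(condition = e@condition, vmax = e@vmax, kA = e@kA, nA = e@nA,
               alpha_lux = e@alphaLux, kA_cv_pct = e@cv[["kA"]],
               nA_cv_pct = e@cv[["nA"]], n = e@n, stringsAsFactors = FALSE)
  }))
  rownames(estimatesTable) <- NULL

  trend <- if (length(conditionEstimates) >= 3L)
    kaCopyNumberTrend(estimatesTable$kA, estimatesTable$n,
                      estimatesTable$condition) else NULL

  sens <- NULL
  if (sensitivity && length(conditionEstimates) >= 3L) {
    sens <- .stage("sensitivity", alphaTetSensitivity(
      curves = lapply(inductionCurves, function(cc)
        cc[, c("dose_nM", "rpu")]),
      ns = as.list(copyNumbers$mean[names(inductionCurves)]),
      vmax = vapply(hillFits, function(f) f@vmax, numeric(1L)),
      constants = constants))
  }

  list(
    wells = wells, scellTable = scellTable,
    doublingTimeTable = doublingTimeTable, copyNumbers = copyNumbers,
    lacIQ = lacIQ, inductionCurves = inductionCurves, hillFits = hillFits,
    conditionEstimates = conditionEstimates, estimatesTable = estimatesTable,
    trend = trend, sensitivity = sens,
    log = list(seed = seed, config = config,
               clipped_points = sum(wells$n_clipped),
               wells_processed = nrow(wells))
  )
}
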