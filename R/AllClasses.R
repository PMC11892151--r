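#' @import methods
#' @importFrom stats median mad sd quantile setNames p.adjust t.test fisher.test
#'   cor.test rnorm runif prcomp complete.cases plogis as.dist qchisq
#'   dhyper rlnorm
#' @importFrom utils packageVersion head tail
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

## ---------------------------------------------------------------------------
## Parameter classes
## ---------------------------------------------------------------------------

#' Parameters for kinetic-trace quantification
#'
#' Bundles the constants needed to turn a microplate absorbance trace into
#' enzyme activity Units: the linear-window acceptance criterion, the molar
#' extinction coefficient of the chromogenic product, and the optical/volume
#' geometry of the assay.
#'
#' @slot r2Min Minimum coefficient of determination for a window to count as
#'   linear (default 0.999).
#' @slot minPoints Minimum number of consecutive readings in a linear window
#'   (default 10, i.e. ten minutes of signal at one reading per minute).
#' @slot epsilon Molar extinction coefficient of the oxidized substrate in
#'   M^-1 cm^-1 (default 36000, oxidized ABTS at 420 nm).
#' @slot pathLength Optical path length in cm. No scientific default exists:
#'   the microplate path depends on fill volume, so it must be supplied.
#'   Computed activities scale as 1/pathLength.
#' @slot reactionVolume Reaction volume in microlitres (default 200).
#' @slot dilutionFactor Fold dilution of the sample before assay (default 1).
#' @slot blankSubtract Whether `quantifyPlate()` subtracts the mean slope of
#'   blank wells from sample slopes (default FALSE).
#'
#' @return A `KineticsParams` object.
#' @examples
#' KineticsParams(pathLength = 1)
#' @export KineticsParams
#' @exportClass KineticsParams
KineticsParams <- setClass("KineticsParams",
  slots = c(
    r2Min = "numeric", minPoints = "integer", epsilon = "numeric",
    pathLength = "numeric", reactionVolume = "numeric",
    dilutionFactor = "numeric", blankSubtract = "logical"
  ),
  prototype = list(
    r2Min = 0.999, minPoints = 10L, epsilon = 36000,
    pathLength = NA_real_, reactionVolume = 200, dilutionFactor = 1,
    blankSubtract = FALSE
  )
)

setValidity("KineticsParams", function(object) {
  msg <- character()
  if (!(length(object@r2Min) == 1L && object@r2Min > 0 && object@r2Min <= 1))
    msg <- c(msg, "r2Min must be a single value in (0, 1]")
  if (!(length(object@minPoints) == 1L && object@minPoints >= 2L))
    msg <- c(msg, "minPoints must be a single integer >= 2")
  for (s in c("epsilon", "reactionVolume", "dilutionFactor")) {
    v <- slot(object, s)
    if (!(length(v) == 1L && is.finite(v) && v > 0))
      msg <- c(msg, sprintf("%s must be a single positive number", s))
  }
  pl <- object@pathLength
  if (!(length(pl) == 1L && (is.na(pl) || pl > 0)))
    msg <- c(msg, "pathLength must be a single positive number (or NA if unset)")
  if (length(msg)) msg else TRUE
})

#' Parameters for primary and secondary hit calling
#'
#' @slot madK Number of scaled median absolute deviations above the median
#'   that defines the primary hit threshold (default 3).
#' @slot madConstant Consistency constant of the MAD (default 1.4826, which
#'   makes the MAD estimate the standard deviation under normality).
#' @slot alpha Significance level for the secondary replicate screen
#'   (default 0.05).
#' @slot alternative Sidedness of the secondary Welch test versus the
#'   reference strain: "greater" (default) or "two.sided".
#' @slot correct Multiplicity correction across strains in the secondary
#'   screen: "none" (default) or "BH".
#'
#' @return A `ScreenParams` object.
#' @examples
#' ScreenParams(madK = 3)
#' @export ScreenParams
#' @exportClass ScreenParams
ScreenParams <- setClass("ScreenParams",
  slots = c(
    madK = "numeric", madConstant = "numeric", alpha = "numeric",
    alternative = "character", correct = "character"
  ),
  prototype = list(
    madK = 3, madConstant = 1.4826, alpha = 0.05,
    alternative = "greater", correct = "none"
  )
)

setValidity("ScreenParams", function(object) {
  msg <- character()
  if (!(length(object@madK) == 1L && object@madK > 0))
    msg <- c(msg, "madK must be a single positive number")
  if (!(length(object@madConstant) == 1L && object@madConstant > 0))
    msg <- c(msg, "madConstant must be a single positive number")
  if (!(length(object@alpha) == 1L && object@alpha > 0 && object@alpha < 1))
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (!object@alternative %in% c("greater", "two.sided"))
    msg <- c(msg, "alternative must be 'greater' or 'two.sided'")
  if (!object@correct %in% c("none", "BH"))
    msg <- c(msg, "correct must be 'none' or 'BH'")
  if (length(msg)) msg else TRUE
})

#' Parameters for comparative-Ct relative quantification
#'
#' @slot targetGene Name of the target transcript (default "ttLCC1").
#' @slot referenceGene Internal reference gene (default "UBC6").
#' @slot calibratorStrain Calibrator strain whose relative level is defined
#'   as 1 (default "BY4741").
#' @slot efficiency Amplification factor per cycle; 2 is the classic
#'   2^-ddCt assumption (default 2).
#'
#' @return A `QpcrParams` object.
#' @examples
#' QpcrParams()
#' @export QpcrParams
#' @exportClass QpcrParams
QpcrParams <- setClass("QpcrParams",
  slots = c(
    targetGene = "character", referenceGene = "character",
    calibratorStrain = "character", efficiency = "numeric"
  ),
  prototype = list(
    targetGene = "ttLCC1", referenceGene = "UBC6",
    calibratorStrain = "BY4741", efficiency = 2
  )
)

setValidity("QpcrParams", function(object) {
  msg <- character()
  if (!(length(object@efficiency) == 1L &&
        object@efficiency > 1 && object@efficiency <= 2))
    msg <- c(msg, "efficiency must lie in (1, 2]")
  for (s in c("targetGene", "referenceGene", "calibratorStrain"))
    if (length(slot(object, s)) != 1L || !nzchar(slot(object, s)))
      msg <- c(msg, sprintf("%s must be a single non-empty string", s))
  if (object@targetGene == object@referenceGene)
    msg <- c(msg, "targetGene and referenceGene must differ")
  if (length(msg)) msg else TRUE
})

#' Parameters for proteome post-processing
#'
#' @slot r2Exclude A biological replicate is excluded when its pairwise R^2
#'   of log-intensities falls below this value against every other replicate
#'   of its strain (default 0.85).
#' @slot imputeQuantile Quantile of each sample's observed intensities at
#'   which left-censored imputation is centred (default 0.05, the bottom 5%).
#' @slot fcMin Minimum fold change for a differential call (default 2).
#' @slot alpha Significance level for differential calls (default 0.05).
#' @slot correction Which p-value the up/down direction filter uses:
#'   "none" uses the raw Welch p (default; BH q-values are still reported),
#'   "BH" filters on the adjusted value.
#' @slot recurrenceFraction Fraction of hit strains in which a protein must
#'   be called in the same direction to pass the recurrence filter
#'   (default 0.5).
#'
#' @return A `ProteomicsParams` object.
#' @examples
#' ProteomicsParams()
#' @export ProteomicsParams
#' @exportClass ProteomicsParams
ProteomicsParams <- setClass("ProteomicsParams",
  slots = c(
    r2Exclude = "numeric", imputeQuantile = "numeric", fcMin = "numeric",
    alpha = "numeric", correction = "character",
    recurrenceFraction = "numeric"
  ),
  prototype = list(
    r2Exclude = 0.85, imputeQuantile = 0.05, fcMin = 2, alpha = 0.05,
    correction = "none", recurrenceFraction = 0.5
  )
)

setValidity("ProteomicsParams", function(object) {
  msg <- character()
  chk01 <- function(v, nm, closed = FALSE) {
    ok <- length(v) == 1L && is.finite(v) &&
      (if (closed) v >= 0 && v <= 1 else v > 0 && v < 1)
    if (!ok) sprintf("%s must lie in %s", nm,
                     if (closed) "[0, 1]" else "(0, 1)") else character()
  }
  msg <- c(msg, chk01(object@r2Exclude, "r2Exclude"),
           chk01(object@imputeQuantile, "imputeQuantile"),
           chk01(object@alpha, "alpha"),
           chk01(object@recurrenceFraction, "recurrenceFraction", closed = TRUE))
  if (!(length(object@fcMin) == 1L && object@fcMin >= 1))
    msg <- c(msg, "fcMin must be a single number >= 1")
  if (!object@correction %in% c("none", "BH"))
    msg <- c(msg, "correction must be 'none' or 'BH'")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Linear fit of a kinetic window
## ---------------------------------------------------------------------------

#' Linear fit over a contiguous kinetic window
#'
#' Result of [trimToLinear()]: the longest contiguous window of a kinetic
#' trace over which a straight line meets the R^2 acceptance criterion,
#' with the fitted slope and intercept. Window indices are 1-based and
#' inclusive.
#'
#' @slot startIndex,endIndex First and last reading of the window (1-based).
#' @slot slope Fitted slope in AU/min.
#' @slot intercept Fitted intercept in AU.
#' @slot rSquared Coefficient of determination, defined as 1 - SSres/SStot;
#'   a window with zero response variance has rSquared 1 by convention and
#'   is flagged `flat`.
#' @slot qcFlag One of "ok", "flat", "no_linear_window".
#'
#' @return A `LinearFit` object.
#' @examples
#' trimToLinear(0:20, 0.01 * (0:20), KineticsParams(pathLength = 1))
#' @export
#' @exportClass LinearFit
LinearFit <- setClass("LinearFit",
  slots = c(
    startIndex = "integer", endIndex = "integer", slope = "numeric",
    intercept = "numeric", rSquared = "numeric", qcFlag = "character"
  )
)

setValidity("LinearFit", function(object) {
  msg <- character()
  if (!object@qcFlag %in% c("ok", "flat", "no_linear_window"))
    msg <- c(msg, "qcFlag must be 'ok', 'flat' or 'no_linear_window'")
  if (object@endIndex < object@startIndex)
    msg <- c(msg, "endIndex must be >= startIndex")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LinearFit", function(object) {
  cat(sprintf(
    "LinearFit: window [%d, %d], slope %.4g AU/min, R^2 %.6f, qc = %s\n",
    object@startIndex, object@endIndex, object@slope, object@rSquared,
    object@qcFlag))
})

## ---------------------------------------------------------------------------
## ORF presence/absence matrix
## ---------------------------------------------------------------------------

#' Strain-by-ORF presence/absence matrix
#'
#' Boolean presence calls for pan-genome ORFs across a strain library, with
#' a designated reference strain (the laboratory strain whose genome defines
#' the baseline gene content).
#'
#' @slot presence Logical matrix, rows = strains, columns = ORFs; no missing
#'   cells, unique dimnames.
#' @slot referenceStrain Identifier of the reference strain; must be a row.
#'
#' @param presence Logical (or 0/1) matrix with strain rownames and ORF
#'   colnames.
#' @param referenceStrain Reference strain identifier.
#' @return An `ORFPresenceMatrix` object.
#' @examples
#' m <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2,
#'             dimnames = list(c("ref", "s1"), c("orfA", "orfB")))
#' ORFPresenceMatrix(m, referenceStrain = "ref")
#' @aliases ORFPresenceMatrix-class
#' @export
ORFPresenceMatrix <- function(presence, referenceStrain) {
  if (is.numeric(presence)) {
    if (!all(presence %in% c(0, 1)))
      stop("presence matrix cells must be logical or 0/1")
    storage.mode(presence) <- "logical"
  }
  new("ORFPresenceMatrix", presence = presence,
      referenceStrain = as.character(referenceStrain))
}

#' @exportClass ORFPresenceMatrix
setClass("ORFPresenceMatrix",
  slots = c(presence = "matrix", referenceStrain = "character"))

setValidity("ORFPresenceMatrix", function(object) {
  p <- object@presence
  msg <- character()
  if (!is.logical(p)) msg <- c(msg, "presence must be a logical matrix")
  if (anyNA(p)) msg <- c(msg, "presence must have no missing cells")
  if (is.null(rownames(p)) || is.null(colnames(p)))
    msg <- c(msg, "presence must have strain rownames and ORF colnames")
  else {
    if (anyDuplicated(rownames(p))) msg <- c(msg, "strain ids must be unique")
    if (anyDuplicated(colnames(p))) msg <- c(msg, "ORF ids must be unique")
    if (length(object@referenceStrain) != 1L ||
        !object@referenceStrain %in% rownames(p))
      msg <- c(msg, "referenceStrain must name exactly one row of presence")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ORFPresenceMatrix", function(object) {
  p <- object@presence
  cat(sprintf(
    "ORFPresenceMatrix: %d strains x %d ORFs (reference: %s)\n",
    nrow(p), ncol(p), object@referenceStrain))
  cat(sprintf("  mean presence rate: %.3f\n", mean(p)))
})

#' @describeIn ORFPresenceMatrix Strain identifiers (row names).
#' @param x,object An `ORFPresenceMatrix`.
#' @export
strainNames <- function(x) rownames(x@presence)

#' @describeIn ORFPresenceMatrix ORF identifiers (column names).
#' @export
orfNames <- function(x) colnames(x@presence)

#' @describeIn ORFPresenceMatrix The designated reference strain.
#' @export
referenceStrain <- function(x) x@referenceStrain

#' @describeIn ORFPresenceMatrix The logical presence matrix.
#' @export
presenceMatrix <- function(x) x@presence

## ---------------------------------------------------------------------------
## Proteome intensity container
## ---------------------------------------------------------------------------

#' Proteome intensity matrix with sample metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `intensity` assay (proteins x samples, positive where observed, `NA` for
#' missing) and per-sample metadata columns `strain_id`, `replicate_id` and
#' `replicate_type` ("technical" or "biological").
#'
#' @param intensity Numeric matrix, rows = proteins, columns = samples.
#' @param sampleInfo `data.frame` (or DataFrame) with one row per sample and
#'   columns `strain_id`, `replicate_id`, `replicate_type`.
#' @return A `ProteomeExperiment`.
#' @examples
#' m <- matrix(c(10, 20, 11, 21), 2,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' info <- data.frame(strain_id = c("A", "A"), replicate_id = c("r1", "r2"),
#'                    replicate_type = "biological")
#' ProteomeExperiment(m, info)
#' @aliases ProteomeExperiment-class
#' @export
ProteomeExperiment <- function(intensity, sampleInfo) {
  sampleInfo <- S4Vectors::DataFrame(sampleInfo)
  if (is.null(rownames(sampleInfo)) ||
      all(rownames(sampleInfo) == as.character(seq_len(nrow(sampleInfo)))))
    rownames(sampleInfo) <- colnames(intensity)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity), colData = sampleInfo)
  new("ProteomeExperiment", se)
}

#' @exportClass ProteomeExperiment
setClass("ProteomeExperiment",
         contains = "SummarizedExperiment")

setValidity("ProteomeExperiment", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'intensity' is required")
  m <- SummarizedExperiment::assay(object, "intensity")
  if (!is.numeric(m)) msg <- c(msg, "intensity assay must be numeric")
  if (any(m[!is.na(m)] <= 0))
    msg <- c(msg, "observed intensities must be positive")
  cd <- SummarizedExperiment::colData(object)
  need <- c("strain_id", "replicate_id", "replicate_type")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("missing sample metadata columns:",
                        paste(miss, collapse = ", ")))
  else {
    if (anyNA(cd[, need]))
      msg <- c(msg, "sample metadata must be complete")
    if (!all(cd$replicate_type %in% c("technical", "biological")))
      msg <- c(msg, "replicate_type must be 'technical' or 'biological'")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProteomeExperiment", function(object) {
  m <- intensities(object)
  cat(sprintf(
    "ProteomeExperiment: %d proteins x %d samples (%d strains), %.1f%% missing\n",
    nrow(m), ncol(m),
    length(unique(SummarizedExperiment::colData(object)$strain_id)),
    100 * mean(is.na(m))))
})

#' @describeIn ProteomeExperiment The intensity assay matrix.
#' @param x A `ProteomeExperiment`.
#' @export
intensities <- function(x) SummarizedExperiment::assay(x, "intensity")

#' @describeIn ProteomeExperiment Sample metadata as a `data.frame`.
#' @export
sampleInfo <- function(x) as.data.frame(SummarizedExperiment::colData(x))

`intensities<-` <- function(x, value) {
  SummarizedExperiment::assay(x, "intensity") <- value
  x
}
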