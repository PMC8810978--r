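#' @import methods
NULL

DIAGNOSIS_LEVELS <- c("TTR-CA", "LC-CA", "none")
CATEGORY_LEVELS <- c("suggestive", "inconclusive", "not_suggestive")

#' PlanarImage: a 2-D planar scintigraphy count grid
#'
#' Container for a planar gamma-camera acquisition: a matrix of detected
#' events per pixel plus the acquisition metadata that matters for H/CL
#' scoring (pixel spacing, time post-injection, projection).
#'
#' @slot counts numeric matrix of nonnegative event counts, indexed
#'   \code{[row, col]} with 1-based pixel centers at integer coordinates.
#' @slot pixelSpacing positive scalar, mm per pixel.
#' @slot timePostInjection acquisition time after tracer injection, hours.
#' @slot projection one of \code{"anterior"}, \code{"posterior"},
#'   \code{"oblique"}.
#'
#' @seealso [PlanarImage()] constructor, [computeHcl()]
#' @export
setClass("PlanarImage",
  representation(
    counts = "matrix",
    pixelSpacing = "numeric",
    timePostInjection = "numeric",
    projection = "character"
  ),
  prototype(
    pixelSpacing = 1,
    timePostInjection = 3,
    projection = "anterior"
  )
)

setValidity("PlanarImage", function(object) {
  msg <- character()
  if (!is.numeric(object@counts)) {
    msg <- c(msg, "counts must be a numeric matrix")
  } else if (anyNA(object@counts) || any(object@counts < 0)) {
    msg <- c(msg, "counts must be nonnegative and non-missing")
  }
  if (length(object@pixelSpacing) != 1 || !is.finite(object@pixelSpacing) ||
      object@pixelSpacing <= 0) {
    msg <- c(msg, "pixelSpacing must be a positive scalar")
  }
  if (length(object@timePostInjection) != 1 ||
      !is.finite(object@timePostInjection) || object@timePostInjection < 0) {
    msg <- c(msg, "timePostInjection must be a nonnegative scalar")
  }
  if (length(object@projection) != 1 ||
      !object@projection %in% c("anterior", "posterior", "oblique")) {
    msg <- c(msg, "projection must be 'anterior', 'posterior' or 'oblique'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PlanarImage
#'
#' @param counts numeric matrix of nonnegative per-pixel event counts.
#' @param pixelSpacing mm per pixel (default 1).
#' @param timePostInjection hours after injection (default 3, the standard
#'   DPD acquisition time for H/CL scoring).
#' @param projection acquisition projection; H/CL is defined on the
#'   anterior projection.
#' @return a [PlanarImage-class] object.
#' @examples
#' img <- PlanarImage(matrix(5, 16, 16))
#' imageCounts(img)[1, 1]
#' @export
PlanarImage <- function(counts, pixelSpacing = 1, timePostInjection = 3,
                        projection = c("anterior", "posterior", "oblique")) {
  projection <- match.arg(projection)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  new("PlanarImage", counts = counts, pixelSpacing = pixelSpacing,
      timePostInjection = timePostInjection, projection = projection)
}

#' CircularROI: a circular region of interest in pixel coordinates
#'
#' The heart ROI and its mirrored contralateral twin are both instances of
#' this class. Pixel membership is decided by the pixel-center rule: a
#' pixel belongs to the ROI when its (integer) center lies within
#' \code{radius} of \code{center}, boundary inclusive.
#'
#' @slot center numeric length-2 \code{(row, col)}, continuous.
#' @slot radius positive radius in pixels.
#' @export
setClass("CircularROI",
  representation(center = "numeric", radius = "numeric")
)

setValidity("CircularROI", function(object) {
  msg <- character()
  if (length(object@center) != 2 || !all(is.finite(object@center))) {
    msg <- c(msg, "center must be a finite (row, col) pair")
  }
  if (length(object@radius) != 1 || !is.finite(object@radius) ||
      object@radius <= 0) {
    msg <- c(msg, "radius must be a positive scalar")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CircularROI
#'
#' @param centerRow,centerCol ROI center in pixel coordinates (continuous).
#' @param radius radius in pixels, > 0.
#' @return a [CircularROI-class] object.
#' @examples
#' roi <- CircularROI(40, 30, 8)
#' mirrorRoi(roi, midlineCol = 50)
#' @export
CircularROI <- function(centerRow, centerCol, radius) {
  new("CircularROI", center = c(centerRow, centerCol), radius = radius)
}

#' HClResult: heart/contralateral quantification result
#'
#' @slot heartCounts total events in the heart ROI (H).
#' @slot contralateralCounts total events in the mirrored ROI (CL).
#' @slot ratio the H/CL ratio.
#' @slot nPixels number of pixels in each ROI (identical by construction).
#' @export
setClass("HClResult",
  representation(
    heartCounts = "numeric",
    contralateralCounts = "numeric",
    ratio = "numeric",
    nPixels = "integer"
  )
)

setValidity("HClResult", function(object) {
  msg <- character()
  if (object@heartCounts < 0 || object@contralateralCounts < 0) {
    msg <- c(msg, "ROI totals must be nonnegative")
  }
  if (object@contralateralCounts > 0 &&
      abs(object@ratio - object@heartCounts / object@contralateralCounts) >
        1e-9 * max(1, object@ratio)) {
    msg <- c(msg, "ratio must equal heartCounts / contralateralCounts")
  }
  if (length(msg)) msg else TRUE
})

#' GradeIntervals: per-grade H/CL mean, SD and count
#'
#' Summary of the H/CL distribution within each Perugini grade (0-3),
#' estimated from a cohort by [fitGradeIntervals()]. Drives the
#' reclassification of equivocal grade-1 studies.
#'
#' @slot mean,sd,n numeric length-4 vectors named \code{"0".."3"}:
#'   arithmetic mean, sample SD (n-1 denominator; \code{NA} when n < 2)
#'   and record count per grade.
#' @export
setClass("GradeIntervals",
  representation(mean = "numeric", sd = "numeric", n = "numeric")
)

setValidity("GradeIntervals", function(object) {
  msg <- character()
  nm <- as.character(0:3)
  for (s in c("mean", "sd", "n")) {
    v <- slot(object, s)
    if (length(v) != 4 || !identical(names(v), nm)) {
      msg <- c(msg, sprintf("%s must be length 4 named '0'..'3'", s))
    }
  }
  if (!length(msg)) {
    if (any(object@sd < 0, na.rm = TRUE)) msg <- c(msg, "sd must be >= 0")
    if (any(object@n < 0)) msg <- c(msg, "n must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' GradeIntervals constructor
#'
#' @param mean,sd,n numeric length-4 vectors (grades 0-3, in order).
#' @return a [GradeIntervals-class] object.
#' @export
GradeIntervals <- function(mean, sd, n) {
  nm <- as.character(0:3)
  mean <- stats::setNames(as.numeric(mean), nm)
  sd <- stats::setNames(as.numeric(sd), nm)
  n <- stats::setNames(as.numeric(n), nm)
  new("GradeIntervals", mean = mean, sd = sd, n = n)
}

#' ThresholdRule: an H/CL cut-off classification rule
#'
#' Two-category rules call a study suggestive of TTR-CA iff
#' H/CL >= cutoff; three-category rules add an inconclusive band
#' \code{[lower, cutoff)} below the cut-off.
#'
#' @slot cutoff H/CL cut-off (suggestive iff ratio >= cutoff).
#' @slot lower lower bound of the inconclusive band (three-category only).
#' @slot mode \code{"two_category"} or \code{"three_category"}.
#' @export
setClass("ThresholdRule",
  representation(cutoff = "numeric", lower = "numeric", mode = "character")
)

setValidity("ThresholdRule", function(object) {
  msg <- character()
  if (!object@mode %in% c("two_category", "three_category")) {
    msg <- c(msg, "mode must be 'two_category' or 'three_category'")
  }
  if (length(object@cutoff) != 1 || !is.finite(object@cutoff) ||
      object@cutoff <= 0) {
    msg <- c(msg, "cutoff must be a positive scalar")
  }
  if (object@mode == "three_category") {
    if (length(object@lower) != 1 || !is.finite(object@lower) ||
        object@lower >= object@cutoff) {
      msg <- c(msg, "three-category rules need lower < cutoff")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ThresholdRule constructor
#'
#' @param cutoff H/CL cut-off value.
#' @param lower lower bound of the inconclusive band; required for
#'   three-category rules (default 1.0, the blood-pool floor).
#' @param mode rule arity.
#' @return a [ThresholdRule-class] object.
#' @examples
#' ThresholdRule(1.3, mode = "two_category")
#' ThresholdRule(1.5, lower = 1.0, mode = "three_category")
#' @export
ThresholdRule <- function(cutoff, lower = 1.0,
                          mode = c("two_category", "three_category")) {
  mode <- match.arg(mode)
  new("ThresholdRule", cutoff = cutoff, lower = lower, mode = mode)
}

#' ConfusionTable: 2x2 diagnostic counts
#'
#' @slot tp,fp,tn,fn nonnegative counts. Disease-positive means a final
#'   diagnosis of TTR-CA; everything else (LC-CA, no amyloidosis) is
#'   disease-negative.
#' @slot positiveDefinition text describing which rule output counted as
#'   test-positive.
#' @slot diseaseDefinition text; fixed to TTR-CA in this package.
#' @export
setClass("ConfusionTable",
  representation(
    tp = "numeric", fp = "numeric", tn = "numeric", fn = "numeric",
    positiveDefinition = "character", diseaseDefinition = "character"
  ),
  prototype(positiveDefinition = "suggestive", diseaseDefinition = "TTR-CA")
)

setValidity("ConfusionTable", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (length(v) != 4 || any(!is.finite(v)) || any(v < 0) ||
      any(v != round(v))) {
    "tp, fp, tn, fn must be nonnegative integers"
  } else TRUE
})

#' ConfusionTable constructor
#' @param tp,fp,tn,fn nonnegative counts.
#' @param positiveDefinition,diseaseDefinition descriptive labels.
#' @return a [ConfusionTable-class] object.
#' @export
ConfusionTable <- function(tp, fp, tn, fn,
                           positiveDefinition = "suggestive",
                           diseaseDefinition = "TTR-CA") {
  new("ConfusionTable", tp = as.numeric(tp), fp = as.numeric(fp),
      tn = as.numeric(tn), fn = as.numeric(fn),
      positiveDefinition = positiveDefinition,
      diseaseDefinition = diseaseDefinition)
}

#' DiagnosticPerformance: sensitivity and specificity of a rule
#'
#' Percentages are stored at full precision; rounding happens only at
#' reporting time (see [performanceRow()]).
#'
#' @slot sensitivity percent, \code{100 * tp / (tp + fn)}.
#' @slot specificity percent, \code{100 * tn / (tn + fp)}.
#' @slot table the underlying [ConfusionTable-class].
#' @export
setClass("DiagnosticPerformance",
  representation(
    sensitivity = "numeric",
    specificity = "numeric",
    table = "ConfusionTable"
  )
)

setValidity("DiagnosticPerformance", function(object) {
  ok <- function(x) length(x) == 1 && is.finite(x) && x >= 0 && x <= 100
  if (!ok(object@sensitivity) || !ok(object@specificity)) {
    "sensitivity and specificity must be percentages in [0, 100]"
  } else TRUE
})

#' RocCurve: sensitivity/specificity swept over H/CL thresholds
#'
#' Thresholds are the sorted distinct observed H/CL values plus -Inf/+Inf
#' sentinels; a record tests positive at threshold t iff its H/CL >= t.
#'
#' @slot thresholds increasing numeric vector of candidate cut-offs.
#' @slot sensitivities,specificities percent, aligned to thresholds.
#' @slot chosenCutoff the selected operating point (NA until
#'   [optimalCutoff()] is applied).
#' @slot criterion text describing the selection criterion.
#' @export
setClass("RocCurve",
  representation(
    thresholds = "numeric",
    sensitivities = "numeric",
    specificities = "numeric",
    chosenCutoff = "numeric",
    criterion = "character"
  ),
  prototype(chosenCutoff = NA_real_, criterion = NA_character_)
)

setValidity("RocCurve", function(object) {
  msg <- character()
  k <- length(object@thresholds)
  if (length(object@sensitivities) != k ||
      length(object@specificities) != k) {
    msg <- c(msg, "thresholds, sensitivities, specificities lengths differ")
  } else {
    if (is.unsorted(object@thresholds)) {
      msg <- c(msg, "thresholds must be increasing")
    }
    if (any(diff(object@sensitivities) > 1e-9)) {
      msg <- c(msg, "sensitivity must be nonincreasing in the threshold")
    }
  }
  if (length(msg)) msg else TRUE
})

#' KWResult: Kruskal-Wallis test with per-group mean ranks and post-hoc
#' pairwise comparisons
#'
#' @slot statistic the tie-corrected H statistic (chi-squared scale).
#' @slot pValue p-value from the chi-squared limit, df = groups - 1.
#' @slot meanRanks mean pooled midrank per group.
#' @slot posthocP symmetric matrix of pairwise adjusted p-values (NA on
#'   the diagonal), from Dunn's test; see [dunnPosthoc()].
#' @export
setClass("KWResult",
  representation(
    statistic = "numeric",
    pValue = "numeric",
    meanRanks = "numeric",
    posthocP = "matrix"
  )
)

setValidity("KWResult", function(object) {
  msg <- character()
  if (object@statistic < -1e-12) msg <- c(msg, "statistic must be >= 0")
  if (object@pValue < 0 || object@pValue > 1) {
    msg <- c(msg, "pValue must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
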