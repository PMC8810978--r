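#' @include AllClasses.R
NULL

#' Accessors for hclquant classes
#'
#' Small accessor generics: slot access stays behind functions so the
#' internal representation can change without breaking callers.
#'
#' @param object an hclquant S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imageCounts", function(object) standardGeneric("imageCounts"))

#' @rdname accessors
#' @export
setMethod("imageCounts", "PlanarImage", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))

#' @rdname accessors
#' @export
setMethod("pixelSpacing", "PlanarImage", function(object) object@pixelSpacing)

#' @rdname accessors
#' @export
setGeneric("roiCenter", function(object) standardGeneric("roiCenter"))

#' @rdname accessors
#' @export
setMethod("roiCenter", "CircularROI", function(object) object@center)

#' @rdname accessors
#' @export
setGeneric("roiRadius", function(object) standardGeneric("roiRadius"))

#' @rdname accessors
#' @export
setMethod("roiRadius", "CircularROI", function(object) object@radius)

#' @rdname accessors
#' @export
setGeneric("hclRatio", function(object) standardGeneric("hclRatio"))

#' @rdname accessors
#' @export
setMethod("hclRatio", "HClResult", function(object) object@ratio)

#' @rdname accessors
#' @export
setGeneric("heartCounts", function(object) standardGeneric("heartCounts"))

#' @rdname accessors
#' @export
setMethod("heartCounts", "HClResult", function(object) object@heartCounts)

#' @rdname accessors
#' @export
setGeneric("contralateralCounts",
           function(object) standardGeneric("contralateralCounts"))

#' @rdname accessors
#' @export
setMethod("contralateralCounts", "HClResult",
          function(object) object@contralateralCounts)

#' @rdname accessors
#' @export
setGeneric("nPixels", function(object) standardGeneric("nPixels"))

#' @rdname accessors
#' @export
setMethod("nPixels", "HClResult", function(object) object@nPixels)

#' @rdname accessors
#' @export
setGeneric("gradeMeans", function(object) standardGeneric("gradeMeans"))

#' @rdname accessors
#' @export
setMethod("gradeMeans", "GradeIntervals", function(object) object@mean)

#' @rdname accessors
#' @export
setGeneric("gradeSds", function(object) standardGeneric("gradeSds"))

#' @rdname accessors
#' @export
setMethod("gradeSds", "GradeIntervals", function(object) object@sd)

#' @rdname accessors
#' @export
setGeneric("gradeNs", function(object) standardGeneric("gradeNs"))

#' @rdname accessors
#' @export
setMethod("gradeNs", "GradeIntervals", function(object) object@n)

#' @rdname accessors
#' @export
setGeneric("sensitivity", function(object) standardGeneric("sensitivity"))

#' @rdname accessors
#' @export
setMethod("sensitivity", "DiagnosticPerformance",
          function(object) object@sensitivity)

#' @rdname accessors
#' @export
setGeneric("specificity", function(object) standardGeneric("specificity"))

#' @rdname accessors
#' @export
setMethod("specificity", "DiagnosticPerformance",
          function(object) object@specificity)

#' @rdname accessors
#' @export
setGeneric("confusionCounts",
           function(object) standardGeneric("confusionCounts"))

#' @rdname accessors
#' @export
setMethod("confusionCounts", "ConfusionTable", function(object) {
  c(tp = object@tp, fp = object@fp, tn = object@tn, fn = object@fn)
})

#' @rdname accessors
#' @export
setMethod("confusionCounts", "DiagnosticPerformance",
          function(object) confusionCounts(object@table))

#' @rdname accessors
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))

#' @rdname accessors
#' @export
setMethod("rocPoints", "RocCurve", function(object) {
  data.frame(
    threshold = object@thresholds,
    sensitivity = object@sensitivities,
    specificity = object@specificities
  )
})

#' @rdname accessors
#' @export
setGeneric("chosenCutoff", function(object) standardGeneric("chosenCutoff"))

#' @rdname accessors
#' @export
setMethod("chosenCutoff", "RocCurve", function(object) object@chosenCutoff)

#' @rdname accessors
#' @export
setGeneric("kwStatistic", function(object) standardGeneric("kwStatistic"))

#' @rdname accessors
#' @export
setMethod("kwStatistic", "KWResult", function(object) object@statistic)

#' @rdname accessors
#' @export
setGeneric("kwPValue", function(object) standardGeneric("kwPValue"))

#' @rdname accessors
#' @export
setMethod("kwPValue", "KWResult", function(object) object@pValue)

#' @rdname accessors
#' @export
setGeneric("meanRanks", function(object) standardGeneric("meanRanks"))

#' @rdname accessors
#' @export
setMethod("meanRanks", "KWResult", function(object) object@meanRanks)

#' @rdname accessors
#' @export
setGeneric("posthocP", function(object) standardGeneric("posthocP"))

#' @rdname accessors
#' @export
setMethod("posthocP", "KWResult", function(object) object@posthocP)

setMethod("show", "PlanarImage", function(object) {
  d <- dim(object@counts)
  cat(sprintf(
    "PlanarImage: %d x %d pixels, %s projection, %.3g mm/px, %.3g h p.i.\n",
    d[1], d[2], object@projection, object@pixelSpacing,
    object@timePostInjection))
  cat(sprintf("  total counts: %.0f\n", sum(object@counts)))
})

setMethod("show", "CircularROI", function(object) {
  cat(sprintf("CircularROI: center (row %.6g, col %.6g), radius %.6g px\n",
              object@center[1], object@center[2], object@radius))
})

setMethod("show", "HClResult", function(object) {
  cat(sprintf("HClResult: H = %.0f, CL = %.0f (%d px each), H/CL = %.4f\n",
              object@heartCounts, object@contralateralCounts,
              object@nPixels, object@ratio))
})

setMethod("show", "GradeIntervals", function(object) {
  cat("GradeIntervals (H/CL by Perugini grade):\n")
  for (g in as.character(0:3)) {
    cat(sprintf("  grade %s: mean %.3f, sd %s, n %d\n", g, object@mean[g],
                ifelse(is.na(object@sd[g]), "NA",
                       sprintf("%.3f", object@sd[g])),
                as.integer(object@n[g])))
  }
})

setMethod("show", "ConfusionTable", function(object) {
  cat(sprintf(
    "ConfusionTable (disease = %s, positive = %s):\n  tp %d  fp %d  tn %d  fn %d\n",
    object@diseaseDefinition, object@positiveDefinition,
    as.integer(object@tp), as.integer(object@fp),
    as.integer(object@tn), as.integer(object@fn)))
})

setMethod("show", "DiagnosticPerformance", function(object) {
  cat(sprintf("DiagnosticPerformance: sensitivity %.1f%%, specificity %.1f%%\n",
              object@sensitivity, object@specificity))
  show(object@table)
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d thresholds", length(object@thresholds)))
  if (!is.na(object@chosenCutoff)) {
    cat(sprintf(", chosen cutoff %.4g (%s)", object@chosenCutoff,
                object@criterion))
  }
  cat("\n")
})

setMethod("show", "KWResult", function(object) {
  cat(sprintf("Kruskal-Wallis: chi-squared %.2f, p %s\n", object@statistic,
              format.pval(object@pValue, digits = 3, eps = 1e-3)))
  cat("  mean ranks:",
      paste(sprintf("%s=%.2f", names(object@meanRanks), object@meanRanks),
            collapse = ", "), "\n")
})
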