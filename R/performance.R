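#' @include AllClasses.R classify.R
NULL

#' Confusion counts for a classified cohort
#'
#' Disease-positive is a final diagnosis of TTR-CA; LC-CA and
#' non-amyloidosis count as disease-negative. Test-positive is
#' membership of \code{positive} (by default only \code{suggestive});
#' inconclusive studies therefore count as test-negative unless they are
#' added to \code{positive} or dropped via \code{excludeInconclusive}.
#' Counting inconclusives as negative is what reproduces the printed
#' performance of these rules (e.g. 76/81 TTR-CA positive at the 1.3
#' cut-off).
#'
#' @param records cohort data.frame.
#' @param categories factor/character of per-record rule outputs, aligned
#'   with \code{records}.
#' @param positive categories counting as test-positive.
#' @param excludeInconclusive drop inconclusive records before counting.
#' @return a [ConfusionTable-class].
#' @examples
#' coh <- referenceCohort()
#' visual <- ifelse(coh$visual_grade >= 2, "suggestive", "not_suggestive")
#' confusion(coh, visual)
#' @export
confusion <- function(records, categories, positive = "suggestive",
                      excludeInconclusive = FALSE) {
  checkCohort(records)
  categories <- as.character(categories)
  if (length(categories) != nrow(records)) {
    stop("categories must align with records (length mismatch)")
  }
  if (!all(categories %in% CATEGORY_LEVELS)) {
    stop("unknown category; expected ",
         paste(CATEGORY_LEVELS, collapse = ", "))
  }
  keep <- if (excludeInconclusive) categories != "inconclusive"
          else rep(TRUE, length(categories))
  disease <- records$diagnosis[keep] == "TTR-CA"
  testPos <- categories[keep] %in% positive
  ConfusionTable(
    tp = sum(disease & testPos),
    fp = sum(!disease & testPos),
    tn = sum(!disease & !testPos),
    fn = sum(disease & !testPos),
    positiveDefinition = paste(positive, collapse = "+")
  )
}

#' Sensitivity and specificity from a confusion table
#'
#' \code{sensitivity = 100 tp / (tp + fn)}, \code{specificity =
#' 100 tn / (tn + fp)}, kept at full precision; round only when
#' reporting (see [performanceRow()]).
#'
#' @param table a [ConfusionTable-class] with nonempty margins.
#' @return a [DiagnosticPerformance-class].
#' @examples
#' sensSpec(ConfusionTable(tp = 73, fp = 1, tn = 88, fn = 8))
#' @export
sensSpec <- function(table) {
  validObject(table)
  if (table@tp + table@fn == 0 || table@tn + table@fp == 0) {
    stop("undefined metric: a confusion-table margin is empty")
  }
  new("DiagnosticPerformance",
      sensitivity = 100 * table@tp / (table@tp + table@fn),
      specificity = 100 * table@tn / (table@tn + table@fp),
      table = table)
}

#' Report a performance row with explicit rounding
#'
#' Rounds half away from zero, so 98.876 reports as 99 at 0 digits.
#'
#' @param perf a [DiagnosticPerformance-class].
#' @param digits decimal places (0 for summary-table style, 1 elsewhere).
#' @param rule label for the row.
#' @return one-row data.frame: rule, sensitivity, specificity.
#' @export
performanceRow <- function(perf, digits = 0, rule = "rule") {
  data.frame(
    rule = rule,
    sensitivity = roundHalfUp(perf@sensitivity, digits),
    specificity = roundHalfUp(perf@specificity, digits),
    stringsAsFactors = FALSE
  )
}

#' ROC curve over observed H/CL values
#'
#' Candidate thresholds are the sorted distinct observed ratios plus
#' -Inf/+Inf sentinels; at each threshold a record tests positive iff
#' its H/CL >= threshold. Sensitivity is nonincreasing and specificity
#' nondecreasing along the sweep.
#'
#' @param records cohort data.frame with \code{hcl} set and at least one
#'   TTR-CA and one non-TTR-CA record.
#' @return a [RocCurve-class].
#' @examples
#' coh <- generateCohort(CohortParams(), seed = 1)
#' roc <- rocCurve(coh)
#' head(rocPoints(roc))
#' @export
rocCurve <- function(records) {
  checkCohort(records)
  if (anyNA(records$hcl)) stop("records with missing hcl cannot enter a ROC")
  disease <- records$diagnosis == "TTR-CA"
  if (!any(disease) || all(disease)) {
    stop("ROC needs at least one diseased and one non-diseased record")
  }
  thr <- c(-Inf, sort(unique(records$hcl)), Inf)
  # counts by sorted-order bookkeeping: #(x >= t) = n - #(x < t)
  dis <- sort(records$hcl[disease])
  nod <- sort(records$hcl[!disease])
  sens <- 100 * (length(dis) - findInterval(thr, dis, left.open = TRUE)) /
    length(dis)
  spec <- 100 * findInterval(thr, nod, left.open = TRUE) / length(nod)
  new("RocCurve", thresholds = thr, sensitivities = sens,
      specificities = spec)
}

#' Select an operating cut-off on a ROC curve
#'
#' \code{"max_sens_hold_spec"} keeps only thresholds whose specificity is
#' at least \code{referenceSpec} (e.g. the specificity achieved at the
#' conventional 1.5 cut-off) and among them returns the smallest
#' threshold attaining the maximal sensitivity - the logic that lowers
#' 1.5 to 1.3 without giving up specificity. \code{"youden"} maximizes
#' sensitivity + specificity - 100, breaking ties toward the larger
#' threshold.
#'
#' @param roc a [RocCurve-class].
#' @param criterion selection criterion.
#' @param referenceSpec percent; required for \code{max_sens_hold_spec}.
#' @return the chosen [RocCurve-class] with \code{chosenCutoff} set; the
#'   cutoff is \code{NA} (with a warning) when no threshold meets
#'   \code{referenceSpec}.
#' @export
optimalCutoff <- function(roc, criterion = c("max_sens_hold_spec", "youden"),
                          referenceSpec = NULL) {
  criterion <- match.arg(criterion)
  validObject(roc)
  thr <- roc@thresholds
  if (!length(thr)) stop("empty ROC curve")
  if (criterion == "max_sens_hold_spec") {
    if (is.null(referenceSpec)) {
      stop("max_sens_hold_spec needs a referenceSpec")
    }
    ok <- roc@specificities >= referenceSpec - 1e-9
    if (!any(ok)) {
      warning("no feasible cutoff: no threshold reaches the reference ",
              "specificity")
      cut <- NA_real_
    } else {
      best <- max(roc@sensitivities[ok])
      cand <- thr[ok & abs(roc@sensitivities - best) <= 1e-9]
      cut <- min(cand)
    }
    crit <- sprintf("max sensitivity holding specificity >= %.4g",
                    referenceSpec)
  } else {
    j <- roc@sensitivities + roc@specificities - 100
    cand <- thr[abs(j - max(j)) <= 1e-9]
    cut <- max(cand)
    crit <- "Youden J"
  }
  initialize(roc, chosenCutoff = cut, criterion = crit)
}
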