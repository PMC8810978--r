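#' @include AllClasses.R cohort.R
NULL

#' ASNC three-category classification
#'
#' Combines the Perugini visual grade and the H/CL ratio into the
#' consensus categories: \emph{suggestive} of TTR-CA when the grade is 2
#' or 3 or H/CL >= 1.5; \emph{inconclusive} when the grade is 1 or H/CL
#' lies in [1.0, 1.5); \emph{not suggestive} when the grade is 0 and
#' H/CL < 1. Each category is a disjunction, so conflicting signals are
#' resolved by precedence: any suggestive clause wins, then any
#' inconclusive clause. The printed band "1 to 1.49" is read as the
#' half-open interval [1.0, 1.5) at full precision, leaving no gap
#' between 1.49 and 1.50.
#'
#' @param visualGrade integer vector of Perugini grades 0-3.
#' @param hcl numeric vector of H/CL ratios (> 0), recycled against
#'   \code{visualGrade}.
#' @return factor with levels suggestive, inconclusive, not_suggestive.
#' @examples
#' classifyAsnc(c(3, 0, 1, 0), c(2.40, 0.98, 1.32, 1.6))
#' @export
classifyAsnc <- function(visualGrade, hcl) {
  stopifnotGrades(visualGrade)
  if (any(!is.finite(hcl)) || any(hcl <= 0)) {
    stop("hcl must be a positive finite ratio")
  }
  n <- max(length(visualGrade), length(hcl))
  visualGrade <- rep_len(visualGrade, n)
  hcl <- rep_len(hcl, n)
  out <- ifelse(visualGrade >= 2 | hcl >= 1.5, "suggestive",
         ifelse(visualGrade == 1 | hcl >= 1.0, "inconclusive",
                "not_suggestive"))
  factor(out, levels = CATEGORY_LEVELS)
}

#' Classify by an H/CL threshold rule
#'
#' Two-category rules: suggestive iff H/CL >= cutoff, else not
#' suggestive. Three-category rules add an inconclusive band
#' [lower, cutoff). Boundary handling is inclusive at the cut-off,
#' matching the ">=" convention of the ASNC rule.
#'
#' @param hcl numeric vector of H/CL ratios (> 0).
#' @param rule a [ThresholdRule-class].
#' @return factor with levels suggestive, inconclusive, not_suggestive.
#' @examples
#' classifyThreshold(c(1.30, 1.29), ThresholdRule(1.3, mode = "two_category"))
#' classifyThreshold(1.10, ThresholdRule(1.3, 1.0, "three_category"))
#' @export
classifyThreshold <- function(hcl, rule) {
  validObject(rule)
  if (any(!is.finite(hcl)) || any(hcl <= 0)) {
    stop("hcl must be a positive finite ratio")
  }
  out <- if (rule@mode == "two_category") {
    ifelse(hcl >= rule@cutoff, "suggestive", "not_suggestive")
  } else {
    ifelse(hcl >= rule@cutoff, "suggestive",
    ifelse(hcl >= rule@lower, "inconclusive", "not_suggestive"))
  }
  factor(out, levels = CATEGORY_LEVELS)
}

#' Fit per-grade H/CL intervals from a cohort
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' the H/CL ratio within each Perugini grade. A grade with a single
#' record gets an undefined (NA) SD, never zero; a grade with no records
#' gets NA mean and SD.
#'
#' @param records cohort data.frame (columns \code{visual_grade},
#'   \code{hcl}).
#' @return a [GradeIntervals-class].
#' @examples
#' coh <- generateCohort(CohortParams(), seed = 1)
#' fitGradeIntervals(coh)
#' @export
fitGradeIntervals <- function(records) {
  checkCohort(records)
  if (nrow(records) == 0) stop("cannot fit intervals on an empty cohort")
  if (anyNA(records$hcl)) stop("records with missing hcl cannot be fitted")
  m <- s <- n <- numeric(4)
  for (g in 0:3) {
    x <- records$hcl[records$visual_grade == g]
    n[g + 1] <- length(x)
    m[g + 1] <- if (length(x)) mean(x) else NA_real_
    s[g + 1] <- if (length(x) >= 2) stats::sd(x) else NA_real_
  }
  GradeIntervals(mean = m, sd = s, n = n)
}

#' Reclassify equivocal (grade 1) studies from their H/CL
#'
#' Assigns each H/CL value to the Perugini grade whose cohort-estimated
#' interval it falls in. The default \code{"nearest_mean"} variant picks
#' the grade minimizing \code{|hcl - mean_g|}; the
#' \code{"standardized"} variant minimizes \code{|hcl - mean_g| / sd_g},
#' probing the ambiguity left by the overlapping per-grade intervals.
#' Ties break toward the lower grade (conservative: fewer false TTR-CA
#' calls). With strictly increasing grade means the assignment is
#' nondecreasing in H/CL.
#'
#' @param hcl numeric vector of H/CL ratios.
#' @param intervals a [GradeIntervals-class] with all four means defined
#'   (the standardized variant additionally needs positive SDs).
#' @param method assignment variant.
#' @return integer vector of grades 0-3.
#' @examples
#' iv <- GradeIntervals(mean = c(0.98, 1.32, 1.54, 2.40),
#'                      sd = c(0.11, 0.40, 0.35, 0.76),
#'                      n = c(77, 19, 7, 67))
#' reclassifyGrade1(c(0.95, 1.43, 2.40), iv)
#' @export
reclassifyGrade1 <- function(hcl, intervals,
                             method = c("nearest_mean", "standardized")) {
  method <- match.arg(method)
  validObject(intervals)
  m <- intervals@mean
  if (anyNA(m)) stop("all four grade means must be defined")
  if (any(!is.finite(hcl)) || any(hcl <= 0)) {
    stop("hcl must be a positive finite ratio")
  }
  w <- rep(1, 4)
  if (method == "standardized") {
    s <- intervals@sd
    if (anyNA(s) || any(s <= 0)) {
      stop("standardized reclassification needs positive SDs for all grades")
    }
    w <- 1 / s
  }
  vapply(hcl, function(x) {
    d <- abs(x - m) * w
    # which.min already breaks ties toward the first (lower) grade
    as.integer(which.min(d) - 1L)
  }, integer(1))
}

#' Tabulate the grade-1 reclassification flow of a cohort
#'
#' Applies [reclassifyGrade1()] to the grade-1 records of a cohort (with
#' intervals fitted on the full cohort unless supplied) and tabulates
#' where they move, by final diagnosis.
#'
#' @param records cohort data.frame.
#' @param intervals optional precomputed [GradeIntervals-class].
#' @param method passed to [reclassifyGrade1()].
#' @return a data.frame with columns \code{patient_id}, \code{diagnosis},
#'   \code{hcl}, \code{new_grade}.
#' @export
reclassificationFlow <- function(records, intervals = NULL,
                                 method = c("nearest_mean", "standardized")) {
  method <- match.arg(method)
  checkCohort(records)
  if (is.null(intervals)) intervals <- fitGradeIntervals(records)
  g1 <- records[records$visual_grade == 1, , drop = FALSE]
  data.frame(
    patient_id = g1$patient_id,
    diagnosis = g1$diagnosis,
    hcl = g1$hcl,
    new_grade = if (nrow(g1)) reclassifyGrade1(g1$hcl, intervals, method)
                else integer(),
    stringsAsFactors = FALSE
  )
}
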