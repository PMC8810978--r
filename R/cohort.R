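#' @include AllClasses.R utils.R phantom.R
NULL

#' CohortParams: synthetic patient-cohort parameters
#'
#' Defaults reproduce the derivation cohort this package's rules were
#' calibrated on: 170 patients split (77, 19, 7, 67) across Perugini
#' grades 0-3, per-grade H/CL levels 0.98 +/- 0.11, 1.32 +/- 0.40,
#' 1.54 +/- 0.35 and 2.40 +/- 0.76, and the empirical grade-wise final
#' diagnosis mix (e.g. grade 1: 8/19 TTR-CA, 5/19 LC-CA, 6/19 none).
#'
#' @slot nPerGrade integer length-4: records per grade 0-3.
#' @slot hclMean,hclSd length-4: per-grade H/CL mean and SD (dimensionless).
#' @slot diagnosisMix 4x3 matrix of proportions, rows = grades 0-3,
#'   columns = TTR-CA, LC-CA, none; each row sums to 1.
#' @slot hclFloor minimum admissible H/CL; per-grade values are drawn from
#'   a normal law truncated below at this floor.
#' @export
setClass("CohortParams",
  representation(
    nPerGrade = "numeric",
    hclMean = "numeric",
    hclSd = "numeric",
    diagnosisMix = "matrix",
    hclFloor = "numeric"
  )
)

setValidity("CohortParams", function(object) {
  msg <- character()
  if (length(object@nPerGrade) != 4 || any(object@nPerGrade < 0) ||
      any(object@nPerGrade != round(object@nPerGrade))) {
    msg <- c(msg, "nPerGrade must be 4 nonnegative integers")
  }
  if (length(object@hclMean) != 4 || length(object@hclSd) != 4 ||
      any(object@hclSd < 0)) {
    msg <- c(msg, "hclMean/hclSd must be length 4 with SDs >= 0")
  }
  if (!all(dim(object@diagnosisMix) == c(4, 3)) ||
      any(object@diagnosisMix < 0) ||
      any(abs(rowSums(object@diagnosisMix) - 1) > 1e-6)) {
    msg <- c(msg, "diagnosisMix must be 4x3 with rows summing to 1")
  }
  if (length(object@hclFloor) != 1 || object@hclFloor <= 0) {
    msg <- c(msg, "hclFloor must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct cohort parameters
#'
#' @param nPerGrade records per Perugini grade 0-3.
#' @param hclMean,hclSd per-grade H/CL mean and SD.
#' @param diagnosisMix 4x3 matrix (grades x TTR-CA/LC-CA/none) of
#'   diagnosis proportions per grade, rows summing to 1.
#' @param hclFloor truncation bound for the H/CL draw; the default 0.5
#'   keeps ratios physical while clipping essentially no mass except in
#'   the wide grade-1 distribution.
#' @return a [CohortParams-class] object.
#' @export
CohortParams <- function(nPerGrade = c(77, 19, 7, 67),
                         hclMean = c(0.98, 1.32, 1.54, 2.40),
                         hclSd = c(0.11, 0.40, 0.35, 0.76),
                         diagnosisMix = rbind(
                           c(0, 3, 74) / 77,
                           c(8, 5, 6) / 19,
                           c(7, 0, 0) / 7,
                           c(66, 1, 0) / 67
                         ),
                         hclFloor = 0.5) {
  dimnames(diagnosisMix) <- list(as.character(0:3), DIAGNOSIS_LEVELS)
  new("CohortParams", nPerGrade = nPerGrade, hclMean = hclMean,
      hclSd = hclSd, diagnosisMix = diagnosisMix, hclFloor = hclFloor)
}

# Largest-remainder allocation of n records to the mix proportions: the
# realized composition is the closest integer composition to n * mix, so
# integer-valued expected counts (as in the default parameterization) are
# hit exactly.
allocateDiagnoses <- function(n, mix) {
  if (n == 0) return(character())
  exact <- n * mix
  base <- floor(exact + 1e-9)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(DIAGNOSIS_LEVELS, times = base)
}

#' Generate a synthetic patient cohort
#'
#' Per grade, H/CL values are drawn from a normal law truncated below at
#' \code{hclFloor} with the configured mean/SD, and final-diagnosis labels
#' are assigned by largest-remainder allocation of the grade's diagnosis
#' mix, shuffled within the grade. Grade counts match \code{nPerGrade}
#' exactly. One root seed drives independent per-grade child streams, so
#' the draw is reproducible record for record.
#'
#' @param params a [CohortParams-class] object.
#' @param seed integer root seed.
#' @return a data.frame with columns \code{patient_id}, \code{visual_grade},
#'   \code{hcl}, \code{diagnosis} (one row per patient).
#' @examples
#' coh <- generateCohort(CohortParams(), seed = 1)
#' table(coh$visual_grade)
#' @export
generateCohort <- function(params = CohortParams(), seed) {
  validObject(params)
  if (all(params@nPerGrade == 0)) {
    stop("empty cohort: nPerGrade is all zero")
  }
  parts <- lapply(0:3, function(g) {
    n <- params@nPerGrade[g + 1]
    if (n == 0) {
      return(NULL)
    }
    withSeed(deriveSeed(seed, g + 1), {
      hcl <- rtruncnormFloor(n, params@hclMean[g + 1], params@hclSd[g + 1],
                             params@hclFloor)
      diag <- sample(allocateDiagnoses(n, params@diagnosisMix[g + 1, ]))
      data.frame(
        visual_grade = rep(g, n),
        hcl = hcl,
        diagnosis = diag,
        stringsAsFactors = FALSE
      )
    })
  })
  cohort <- do.call(rbind, parts)
  cohort <- data.frame(
    patient_id = sprintf("P%03d", seq_len(nrow(cohort))),
    cohort,
    stringsAsFactors = FALSE
  )
  rownames(cohort) <- NULL
  cohort
}

#' The built-in 170-patient reference cohort (grade-level)
#'
#' Deterministic grade-by-diagnosis contingency skeleton of the derivation
#' cohort: 170 patients of whom 81 were TTR-CA (66 grade 3, 7 grade 2,
#' 8 grade 1), 9 LC-CA (1 grade 3, 5 grade 1, 3 grade 0) and 80 without
#' cardiac amyloidosis (6 grade 1, 74 grade 0). H/CL is \code{NA}: the
#' skeleton supports grade-level evaluation (the visual rule) only.
#'
#' @return a data.frame with columns \code{patient_id}, \code{visual_grade},
#'   \code{hcl} (all \code{NA}), \code{diagnosis}.
#' @examples
#' coh <- referenceCohort()
#' table(coh$visual_grade, coh$diagnosis)
#' @export
referenceCohort <- function() {
  cells <- data.frame(
    visual_grade = c(3L, 2L, 1L, 3L, 1L, 0L, 1L, 0L),
    diagnosis = c("TTR-CA", "TTR-CA", "TTR-CA",
                  "LC-CA", "LC-CA", "LC-CA",
                  "none", "none"),
    n = c(66L, 7L, 8L, 1L, 5L, 3L, 6L, 74L),
    stringsAsFactors = FALSE
  )
  idx <- rep(seq_len(nrow(cells)), cells$n)
  cohort <- data.frame(
    visual_grade = cells$visual_grade[idx],
    hcl = NA_real_,
    diagnosis = cells$diagnosis[idx],
    stringsAsFactors = FALSE
  )
  cohort <- cohort[order(cohort$visual_grade,
                         match(cohort$diagnosis, DIAGNOSIS_LEVELS)), ]
  data.frame(
    patient_id = sprintf("R%03d", seq_len(nrow(cohort))),
    cohort,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Reference cohort with band-representative H/CL values
#'
#' Extends [referenceCohort()] with H/CL values reconstructed from the
#' classification margins reported for the derivation cohort. Patient-level
#' ratios were never published; each patient instead receives a value
#' representative of the H/CL band its reported classification implies:
#' \itemize{
#'   \item 1.60 - the 75 patients suggestive at the 1.5 cut-off
#'     (73 TTR-CA, 2 LC-CA);
#'   \item 1.40 - the 4 inconclusive patients reclassified as suggestive
#'     when the cut-off moves to 1.3 (3 TTR-CA confirmed, 1 rejected);
#'   \item 1.10 - the 41 patients inconclusive at both cut-offs
#'     (5 TTR-CA, 3 LC-CA, 33 none);
#'   \item 0.90 - the 50 patients below 1.0 (3 LC-CA, 47 none).
#' }
#' The band totals reproduce the reported margins exactly (75 suggestive
#' at 1.5; 76/81 TTR-CA positive at 1.3; 45 and 41 inconclusive at 1.5
#' and 1.3); the within-band values are placeholders, so only analyses
#' that depend on band membership (threshold rules, confusion counts) are
#' meaningful on this fixture.
#'
#' @return a data.frame like [referenceCohort()] with \code{hcl} set.
#' @examples
#' coh <- referenceCohortHcl()
#' table(classifyThreshold(coh$hcl, ThresholdRule(1.5, 1.0, "three_category")))
#' @export
referenceCohortHcl <- function() {
  cohort <- referenceCohort()
  bands <- list(
    list(hcl = 1.60, n = c("TTR-CA" = 73, "LC-CA" = 2, "none" = 0)),
    list(hcl = 1.40, n = c("TTR-CA" = 3, "LC-CA" = 1, "none" = 0)),
    list(hcl = 1.10, n = c("TTR-CA" = 5, "LC-CA" = 3, "none" = 33)),
    list(hcl = 0.90, n = c("TTR-CA" = 0, "LC-CA" = 3, "none" = 47))
  )
  for (dx in DIAGNOSIS_LEVELS) {
    # fill highest grades first so suggestive values land on grades 3/2
    rows <- which(cohort$diagnosis == dx)
    rows <- rows[order(-cohort$visual_grade[rows])]
    vals <- unlist(lapply(bands, function(b) rep(b$hcl, b$n[[dx]])))
    stopifnot(length(vals) == length(rows))
    cohort$hcl[rows] <- vals
  }
  cohort
}

checkCohort <- function(records) {
  need <- c("patient_id", "visual_grade", "hcl", "diagnosis")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("cohort must be a data.frame with columns ",
         paste(need, collapse = ", "))
  }
  stopifnotGrades(records$visual_grade)
  if (!all(records$diagnosis %in% DIAGNOSIS_LEVELS)) {
    stop("diagnosis must be one of ", paste(DIAGNOSIS_LEVELS, collapse = ", "))
  }
  invisible(records)
}
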