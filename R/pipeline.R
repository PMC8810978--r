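#' @include AllClasses.R phantom.R cohort.R roi.R classify.R performance.R stats.R io.R
NULL

#' Append classification columns to a cohort
#'
#' Adds a \code{category} column (the ASNC three-category call when
#' \code{rule} is NULL, otherwise the threshold-rule call) and a
#' \code{reclassified_grade} column: the visual grade, with grade-1
#' records reassigned through [reclassifyGrade1()] using intervals
#' fitted on the cohort unless supplied.
#'
#' @param records cohort data.frame with \code{hcl} set.
#' @param rule optional [ThresholdRule-class]; NULL selects the combined
#'   ASNC rule.
#' @param intervals optional [GradeIntervals-class].
#' @param method reclassification variant, see [reclassifyGrade1()].
#' @return the cohort with \code{category} and \code{reclassified_grade}
#'   appended.
#' @export
classifyCohort <- function(records, rule = NULL, intervals = NULL,
                           method = c("nearest_mean", "standardized")) {
  method <- match.arg(method)
  checkCohort(records)
  if (anyNA(records$hcl)) stop("classifyCohort needs hcl on every record")
  records$category <- as.character(
    if (is.null(rule)) classifyAsnc(records$visual_grade, records$hcl)
    else classifyThreshold(records$hcl, rule)
  )
  if (is.null(intervals)) intervals <- fitGradeIntervals(records)
  records$reclassified_grade <- records$visual_grade
  g1 <- records$visual_grade == 1
  if (any(g1)) {
    records$reclassified_grade[g1] <-
      reclassifyGrade1(records$hcl[g1], intervals, method)
  }
  records
}

#' Default run configuration
#'
#' A plain named list mirroring the JSON run-configuration schema:
#' \code{seed}, \code{output_dir}, \code{phantom} (geometry and rates),
#' \code{cohort} (sizes, H/CL moments, diagnosis mix), \code{roi}
#' (\code{center_row, center_col, radius, midline_col}), \code{rules}
#' (threshold list, ASNC toggle, reclassification variant) and
#' \code{evaluation} (reference specificity source, report digits).
#'
#' @param seed integer seed.
#' @param output_dir output directory.
#' @return a validated config list.
#' @export
defaultRunConfig <- function(seed = 1L, output_dir = "hclquant-run") {
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    phantom = list(),
    cohort = list(),
    roi = NULL,
    rules = list(
      asnc = TRUE,
      thresholds = list(
        list(cutoff = 1.5, lower = 1.0, mode = "three_category"),
        list(cutoff = 1.3, lower = 1.0, mode = "three_category"),
        list(cutoff = 1.3, mode = "two_category"),
        list(cutoff = 1.0, mode = "two_category")
      ),
      reclassification = "nearest_mean"
    ),
    evaluation = list(reference_cutoff = 1.5, digits = 0)
  )
}

#' Read a JSON run configuration
#'
#' Fields missing from the file fall back to [defaultRunConfig()]
#' values; unknown fields are rejected.
#'
#' @param path JSON file path.
#' @return a validated config list.
#' @export
readRunConfig <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
  cfg <- defaultRunConfig()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown run-config field(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  validateRunConfig(cfg)
}

validateRunConfig <- function(cfg) {
  if (length(cfg$seed) != 1 || is.na(suppressWarnings(as.integer(cfg$seed)))) {
    stop("config: seed must be a single integer")
  }
  cfg$seed <- as.integer(cfg$seed)
  if (!is.character(cfg$output_dir) || length(cfg$output_dir) != 1) {
    stop("config: output_dir must be a single path")
  }
  # JSON configs use snake_case field names; constructors use camelCase
  toCamel <- function(lst) {
    if (length(lst)) {
      names(lst) <- gsub("_(\\w)", "\\U\\1", names(lst), perl = TRUE)
    }
    lst
  }
  cfg$phantomParams <- do.call(PhantomParams, toCamel(cfg$phantom %||% list()))
  coh <- toCamel(cfg$cohort %||% list())
  if (!is.null(coh$diagnosisMix)) {
    coh$diagnosisMix <- matrix(unlist(coh$diagnosisMix), nrow = 4,
                               byrow = TRUE)
  }
  cfg$cohortParams <- do.call(CohortParams, coh)
  cfg$thresholdRules <- lapply(cfg$rules$thresholds, function(r) {
    do.call(ThresholdRule, r)
  })
  if (!cfg$rules$reclassification %in% c("nearest_mean", "standardized")) {
    stop("config: rules$reclassification must be nearest_mean or standardized")
  }
  cfg
}

ruleLabel <- function(rule) {
  if (rule@mode == "two_category") {
    sprintf("hcl>=%.4g (two-category)", rule@cutoff)
  } else {
    sprintf("hcl>=%.4g, inconclusive [%.4g, %.4g)", rule@cutoff,
            rule@lower, rule@cutoff)
  }
}

#' Simulate a cohort and phantom images to disk
#'
#' Writes a seeded 170-row (by default) cohort CSV plus one phantom image
#' per Perugini grade (lossless text grid, JSON sidecar and PNG preview)
#' into the configured output directory, creating it if needed. Running
#' twice with the same config yields byte-identical CSV/JSON outputs.
#'
#' @param config a config list from [defaultRunConfig()] or
#'   [readRunConfig()].
#' @return paths of the written files, invisibly.
#' @export
runSimulate <- function(config = defaultRunConfig()) {
  config <- validateRunConfig(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generateCohort(config$cohortParams, seed = config$seed)
  cohortPath <- file.path(config$output_dir, "cohort.csv")
  writeCohortCsv(cohort, cohortPath)
  imgPaths <- character()
  for (g in 0:3) {
    img <- generatePhantom(g, config$phantomParams,
                           seed = deriveSeed(config$seed, 100 + g))
    base <- file.path(config$output_dir, sprintf("phantom_grade%d", g))
    writePlanarImage(img, paste0(base, ".csv"))
    writePhantomPng(img, paste0(base, ".png"))
    imgPaths <- c(imgPaths, paste0(base, ".csv"))
  }
  invisible(list(cohort = cohortPath, images = imgPaths))
}

#' Evaluate diagnostic rules on a cohort and write report files
#'
#' Runs the full evaluation stage: per-rule sensitivity/specificity
#' (visual rule, ASNC combined rule if enabled, every configured
#' threshold rule), the grade-1 reclassification flow, per-grade
#' interval fit, Kruskal-Wallis with Dunn post-hoc, the ROC sweep and
#' the optimized cut-off holding the reference-rule specificity.
#'
#' @param config a config list.
#' @param cohortCsv path of a cohort CSV; defaults to the one
#'   [runSimulate()] writes.
#' @return invisibly, a list with the computed objects; report files
#'   (performance.csv, reclassification.csv, intervals.json,
#'   kruskal_wallis.json, roc.csv) land in the output directory.
#' @export
runEvaluate <- function(config = defaultRunConfig(),
                        cohortCsv = file.path(config$output_dir,
                                              "cohort.csv")) {
  config <- validateRunConfig(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- readCohortCsv(cohortCsv)
  if (nrow(cohort) == 0) stop("empty cohort")
  digits <- config$evaluation$digits %||% 0

  rows <- list()
  visual <- ifelse(cohort$visual_grade >= 2, "suggestive", "not_suggestive")
  rows$visual <- performanceRow(sensSpec(confusion(cohort, visual)),
                                digits, rule = "visual score")
  haveHcl <- !anyNA(cohort$hcl)
  rocObj <- kw <- intervals <- flow <- NULL
  if (haveHcl) {
    if (isTRUE(config$rules$asnc)) {
      asnc <- classifyAsnc(cohort$visual_grade, cohort$hcl)
      rows$asnc <- performanceRow(sensSpec(confusion(cohort, asnc)),
                                  digits, rule = "ASNC combined")
    }
    for (rule in config$thresholdRules) {
      cat_ <- classifyThreshold(cohort$hcl, rule)
      rows[[ruleLabel(rule)]] <- performanceRow(
        sensSpec(confusion(cohort, cat_)), digits, rule = ruleLabel(rule))
    }
    intervals <- fitGradeIntervals(cohort)
    flow <- reclassificationFlow(cohort, intervals,
                                 method = config$rules$reclassification)
    kw <- kruskalWallisByGrade(cohort)
    rocObj <- rocCurve(cohort)
    refCut <- config$evaluation$reference_cutoff %||% 1.5
    refSpec <- sensSpec(confusion(
      cohort, classifyThreshold(cohort$hcl,
                                ThresholdRule(refCut, 1.0,
                                              "three_category"))))@specificity
    rocObj <- optimalCutoff(rocObj, "max_sens_hold_spec",
                            referenceSpec = refSpec)
  }
  perf <- do.call(rbind, rows)
  rownames(perf) <- NULL
  utils::write.csv(perf, file.path(config$output_dir, "performance.csv"),
                   row.names = FALSE, quote = FALSE)
  if (haveHcl) {
    utils::write.csv(flow,
                     file.path(config$output_dir, "reclassification.csv"),
                     row.names = FALSE, quote = FALSE)
    writeGradeIntervals(intervals,
                        file.path(config$output_dir, "intervals.json"))
    jsonlite::write_json(
      list(statistic = kw@statistic, p_value = kw@pValue,
           mean_ranks = as.list(kw@meanRanks),
           posthoc_adjusted_p = apply(kw@posthocP, 1, as.list)),
      file.path(config$output_dir, "kruskal_wallis.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
    roc <- rocPoints(rocObj)
    roc$chosen <- !is.na(chosenCutoff(rocObj)) &
      roc$threshold == chosenCutoff(rocObj)
    utils::write.csv(roc, file.path(config$output_dir, "roc.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(list(performance = perf, intervals = intervals, flow = flow,
                 kw = kw, roc = rocObj))
}
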