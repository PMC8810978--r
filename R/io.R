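#' @include AllClasses.R cohort.R classify.R
NULL

#' Read / write cohort CSV files
#'
#' The on-disk cohort format is a header CSV with columns
#' \code{patient_id, visual_grade, hcl, diagnosis} (diagnosis spelled
#' \code{TTR-CA}, \code{LC-CA} or \code{none}). Malformed rows are
#' rejected with their row number.
#'
#' @param path file path.
#' @return \code{readCohortCsv}: the validated cohort data.frame.
#' @export
readCohortCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "visual_grade", "hcl", "diagnosis")
  if (!all(need %in% names(df))) {
    stop("cohort CSV must have columns ", paste(need, collapse = ", "))
  }
  badGrade <- which(!(df$visual_grade %in% 0:3))
  if (length(badGrade)) {
    stop("invalid visual_grade in cohort CSV row(s) ",
         paste(badGrade, collapse = ", "))
  }
  badDx <- which(!(df$diagnosis %in% DIAGNOSIS_LEVELS))
  if (length(badDx)) {
    stop("invalid diagnosis in cohort CSV row(s) ",
         paste(badDx, collapse = ", "))
  }
  badHcl <- which(!is.na(df$hcl) & (!is.finite(df$hcl) | df$hcl <= 0))
  if (length(badHcl)) {
    stop("invalid hcl in cohort CSV row(s) ", paste(badHcl, collapse = ", "))
  }
  df[need]
}

#' @rdname readCohortCsv
#' @param records cohort data.frame (possibly with appended
#'   classification columns).
#' @return \code{writeCohortCsv}: the path, invisibly.
#' @export
writeCohortCsv <- function(records, path) {
  checkCohort(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a planar image as plain text plus JSON sidecar
#'
#' The lossless native format: the count grid as a header-free CSV of
#' integers and a \code{.json} sidecar carrying pixel spacing,
#' acquisition time and projection.
#'
#' @param image a [PlanarImage-class].
#' @param path path of the grid file; the sidecar lives at
#'   \code{paste0(path, ".json")}.
#' @return the path, invisibly (writer); a [PlanarImage-class] (reader).
#' @export
writePlanarImage <- function(image, path) {
  validObject(image)
  utils::write.table(image@counts, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(pixel_spacing = image@pixelSpacing,
         time_post_injection = image@timePostInjection,
         projection = image@projection),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePlanarImage
#' @export
readPlanarImage <- function(path) {
  counts <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(counts) <- NULL
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  PlanarImage(counts,
              pixelSpacing = meta$pixel_spacing %||% 1,
              timePostInjection = meta$time_post_injection %||% 3,
              projection = meta$projection %||% "anterior")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an 8-bit PNG preview of a planar image
#'
#' Visualization only: counts are linearly rescaled to the 8-bit range
#' (the lossless grid goes through [writePlanarImage()]).
#'
#' @param image a [PlanarImage-class].
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
writePhantomPng <- function(image, path) {
  validObject(image)
  m <- image@counts
  hi <- max(m, 1)
  png::writePNG(m / hi, path)
  invisible(path)
}

#' Serialize grade intervals to / from JSON
#'
#' Format: \code{{"0": {"mean": ..., "sd": ..., "n": ...}, ...}}.
#'
#' @param intervals a [GradeIntervals-class].
#' @param path output path.
#' @return the path, invisibly (writer); a [GradeIntervals-class] (reader).
#' @export
writeGradeIntervals <- function(intervals, path) {
  validObject(intervals)
  obj <- lapply(as.character(0:3), function(g) {
    list(mean = intervals@mean[[g]], sd = intervals@sd[[g]],
         n = intervals@n[[g]])
  })
  names(obj) <- as.character(0:3)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname writeGradeIntervals
#' @export
readGradeIntervals <- function(path) {
  obj <- jsonlite::read_json(path)
  pick <- function(field) {
    vapply(as.character(0:3), function(g) {
      v <- obj[[g]][[field]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  GradeIntervals(mean = pick("mean"), sd = pick("sd"), n = pick("n"))
}
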