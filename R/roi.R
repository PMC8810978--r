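#' @include AllClasses.R
NULL

#' Mirror a circular ROI across the sternal midline
#'
#' Reflects the ROI center column across \code{midlineCol}
#' (\code{col' = 2 * midlineCol - col}); row and radius are unchanged.
#' The operation is an involution: mirroring twice restores the ROI.
#'
#' @param roi a [CircularROI-class].
#' @param midlineCol pixel column of the sternal axis (may be fractional).
#' @return the mirrored [CircularROI-class].
#' @examples
#' mirrorRoi(CircularROI(40, 30, 8), midlineCol = 50)  # center (40, 70)
#' @export
mirrorRoi <- function(roi, midlineCol) {
  validObject(roi)
  CircularROI(roi@center[1], 2 * midlineCol - roi@center[2], roi@radius)
}

# Integer pixel centers belonging to the ROI (pixel-center-within-radius,
# boundary inclusive). Membership is evaluated on the unbounded integer
# grid; callers decide whether out-of-image members are an error.
roiPixels <- function(roi) {
  r <- roi@radius
  rows <- seq(ceiling(roi@center[1] - r), floor(roi@center[1] + r))
  cols <- seq(ceiling(roi@center[2] - r), floor(roi@center[2] + r))
  if (!length(rows) || !length(cols)) {
    return(cbind(row = integer(), col = integer()))
  }
  grid <- expand.grid(row = rows, col = cols)
  d2 <- (grid$row - roi@center[1])^2 + (grid$col - roi@center[2])^2
  as.matrix(grid[d2 <= r^2 + 1e-9, , drop = FALSE])
}

#' Sum counts inside a circular ROI
#'
#' A pixel contributes iff its center lies within the ROI radius
#' (boundary inclusive). If the ROI disc, by that rule, extends beyond
#' the image an out-of-bounds error is raised rather than silently
#' clipping the region.
#'
#' @param image a [PlanarImage-class].
#' @param roi a [CircularROI-class].
#' @return list with \code{total} (summed counts) and \code{nPixels}.
#' @examples
#' img <- PlanarImage(matrix(7, 20, 20))
#' sumCounts(img, CircularROI(10, 10, 2))  # 13 pixels, total 91
#' @export
sumCounts <- function(image, roi) {
  validObject(image)
  validObject(roi)
  px <- roiPixels(roi)
  cnt <- image@counts
  if (nrow(px) == 0) {
    return(list(total = 0, nPixels = 0L))
  }
  if (any(px[, "row"] < 1) || any(px[, "row"] > nrow(cnt)) ||
      any(px[, "col"] < 1) || any(px[, "col"] > ncol(cnt))) {
    stop("ROI extends beyond the image (pixel-center rule)")
  }
  list(total = sum(cnt[px]), nPixels = nrow(px))
}

#' Compute the heart/contralateral (H/CL) count ratio
#'
#' Sums counts in the heart ROI (H) and in its twin mirrored across the
#' sternal midline (CL), and returns H/CL. Both regions use the same
#' pixel-membership rule and - for integer or half-integer midlines,
#' which this function requires - contain exactly the same number of
#' pixels.
#'
#' H/CL is defined on the anterior projection about 3 h post-injection;
#' other projections or times are accepted with a warning.
#'
#' @param image a [PlanarImage-class].
#' @param heartRoi the cardiac [CircularROI-class].
#' @param midlineCol sternal axis column, a multiple of 0.5; defaults to
#'   the vertical image center.
#' @return an [HClResult-class].
#' @examples
#' img <- generatePhantom(3, PhantomParams(), seed = 7)
#' computeHcl(img, heartRoi(PhantomParams()))
#' @export
computeHcl <- function(image, heartRoi,
                       midlineCol = (ncol(imageCounts(image)) + 1) / 2) {
  validObject(image)
  if (abs(midlineCol * 2 - round(midlineCol * 2)) > 1e-9) {
    stop("midlineCol must be an integer or half-integer column so that ",
         "mirrored ROIs cover identical pixel counts")
  }
  if (image@projection != "anterior") {
    warning("H/CL is defined on the anterior projection; got ",
            image@projection)
  }
  if (abs(image@timePostInjection - 3) > 0.5) {
    warning("H/CL thresholds assume ~3 h post-injection acquisitions; got ",
            image@timePostInjection, " h")
  }
  clRoi <- mirrorRoi(heartRoi, midlineCol)
  h <- sumCounts(image, heartRoi)
  cl <- sumCounts(image, clRoi)
  stopifnot(h$nPixels == cl$nPixels)
  if (cl$total == 0) {
    stop("contralateral ROI has zero counts; H/CL is undefined")
  }
  new("HClResult", heartCounts = h$total, contralateralCounts = cl$total,
      ratio = h$total / cl$total, nPixels = as.integer(h$nPixels))
}

#' Center an ROI on the count-weighted centroid of a search box
#'
#' Convenience placement helper mimicking manual ROI positioning: within
#' a rectangular search box the count-weighted centroid is computed and
#' a circular ROI of the requested radius is centered there.
#'
#' @param image a [PlanarImage-class].
#' @param rowRange,colRange integer ranges (length-2, inclusive) of the
#'   search box.
#' @param radius ROI radius in pixels.
#' @return a [CircularROI-class] centered on the centroid.
#' @export
centerOnCentroid <- function(image, rowRange, colRange, radius) {
  validObject(image)
  cnt <- image@counts
  rows <- seq(max(1, rowRange[1]), min(nrow(cnt), rowRange[2]))
  cols <- seq(max(1, colRange[1]), min(ncol(cnt), colRange[2]))
  sub <- cnt[rows, cols, drop = FALSE]
  tot <- sum(sub)
  if (tot <= 0) stop("search box contains no counts")
  cr <- sum(rowSums(sub) * rows) / tot
  cc <- sum(colSums(sub) * cols) / tot
  CircularROI(cr, cc, radius)
}
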