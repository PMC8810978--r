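#' @include AllClasses.R
NULL

asGradeGroups <- function(hclByGrade) {
  if (is.data.frame(hclByGrade)) {
    checkCohort(hclByGrade)
    hclByGrade <- split(hclByGrade$hcl,
                        factor(hclByGrade$visual_grade, levels = 0:3))
  }
  hclByGrade <- hclByGrade[vapply(hclByGrade, length, 1L) > 0]
  if (length(hclByGrade) < 2) {
    stop("need at least two nonempty groups")
  }
  if (is.null(names(hclByGrade)) || any(names(hclByGrade) == "")) {
    names(hclByGrade) <- paste0("g", seq_along(hclByGrade))
  }
  hclByGrade
}

#' Kruskal-Wallis comparison of H/CL across Perugini grades
#'
#' Rank-based k-group test with midrank tie correction (via
#' [stats::kruskal.test()]); the p-value comes from the chi-squared limit
#' with groups - 1 degrees of freedom. Per-group mean pooled midranks
#' and Dunn post-hoc pairwise p-values are attached.
#'
#' @param hclByGrade either a cohort data.frame (split by
#'   \code{visual_grade}) or a named list of numeric H/CL vectors.
#' @param adjust multiplicity adjustment for the post-hoc matrix.
#' @return a [KWResult-class].
#' @examples
#' coh <- generateCohort(CohortParams(), seed = 1)
#' kruskalWallisByGrade(coh)
#' @export
kruskalWallisByGrade <- function(hclByGrade,
                                 adjust = c("holm", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  groups <- asGradeGroups(hclByGrade)
  kt <- stats::kruskal.test(groups)
  stat <- unname(kt$statistic)
  pval <- unname(kt$p.value)
  if (!is.finite(stat)) {
    # every observation tied: all midranks equal, H is 0 by definition but
    # the tie-correction denominator vanishes in stats::kruskal.test
    stat <- 0
    pval <- 1
  }
  pooled <- rank(unlist(groups, use.names = FALSE))
  idx <- rep(seq_along(groups), vapply(groups, length, 1L))
  mr <- tapply(pooled, idx, mean)
  meanRanks <- stats::setNames(as.numeric(mr), names(groups))
  new("KWResult",
      statistic = stat,
      pValue = pval,
      meanRanks = meanRanks,
      posthocP = dunnPosthoc(groups, adjust = adjust))
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z-statistics on the pooled midranks,
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) /
#'   \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)},}
#' with the tie correction \eqn{T = \sum (t^3 - t) / (12 (N - 1))} over
#' tie groups of size t, two-sided normal p-values and the requested
#' multiplicity adjustment (Holm by default, the standard companion when
#' a Kruskal-Wallis omnibus is followed up).
#'
#' @inheritParams kruskalWallisByGrade
#' @return symmetric matrix of adjusted p-values, diagonal NA.
#' @examples
#' dunnPosthoc(list(g0 = c(1, 1.1), g1 = c(1.3, 1.4), g3 = c(2.2, 2.6)))
#' @export
dunnPosthoc <- function(hclByGrade,
                        adjust = c("holm", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  groups <- asGradeGroups(hclByGrade)
  k <- length(groups)
  x <- unlist(groups, use.names = FALSE)
  n <- vapply(groups, length, 1L)
  N <- length(x)
  pooled <- rank(x)
  idx <- rep(seq_len(k), n)
  rbar <- tapply(pooled, idx, mean)
  ties <- table(x)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  z <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / n[i] + 1 / n[j]))
      z[i, j] <- z[j, i] <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
    }
  }
  pRaw <- 2 * stats::pnorm(-abs(z[upper.tri(z)]))
  pAdj <- stats::p.adjust(pRaw, method = if (adjust == "none") "none"
                                         else adjust)
  p <- matrix(NA_real_, k, k, dimnames = dimnames(z))
  p[upper.tri(p)] <- pAdj
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  p
}
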