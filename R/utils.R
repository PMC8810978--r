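#' Round half away from zero
#'
#' Reporting-time rounding for percentages: 98.876 -> 99 at 0 digits,
#' unlike [round()]'s round-half-even. Values are never rounded before
#' reporting.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @return rounded numeric vector.
#' @examples
#' roundHalfUp(c(89.5, 98.876, 93.83), 0)
#' roundHalfUp(93.827, 1)
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Child-stream derivation from one root seed: stream i gets seed
# (root * 48271 + i) mod (2^31 - 1), a Lehmer-style mixing step. Keeps
# per-grade / per-image draws independent and reproducible while staying
# inside R's 32-bit integer seed range.
deriveSeed <- function(root, index) {
  m <- 2147483647
  as.integer((as.numeric(root) %% m * 48271 + as.numeric(index)) %% m)
}

# Truncated-normal sampling by inverse CDF: exact, deterministic given the
# RNG stream, no rejection loop. sd = 0 degenerates to the mean (which must
# itself satisfy the floor).
rtruncnormFloor <- function(n, mean, sd, floor) {
  if (sd == 0) {
    if (mean < floor) stop("degenerate distribution lies below the floor")
    return(rep(mean, n))
  }
  fl <- stats::pnorm((floor - mean) / sd)
  u <- stats::runif(n, min = fl, max = 1)
  mean + sd * stats::qnorm(u)
}

# Mean of the floor-truncated normal: mean + sd * phi(a) / (1 - Phi(a)).
truncnormMean <- function(mean, sd, floor) {
  if (sd == 0) return(mean)
  a <- (floor - mean) / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

stopifnotGrades <- function(grade) {
  if (anyNA(grade) || !all(grade %in% 0:3)) {
    stop("visual grade must be an integer in 0..3")
  }
}
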