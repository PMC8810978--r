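# Independent brute-force oracles. Deliberately naive (double loops,
# direct formulas) so they share no code path with the implementation.

# per-pixel disc membership and total, looped over the full grid
oracleDiscSum <- function(counts, center, radius) {
  total <- 0
  n <- 0L
  for (r in seq_len(nrow(counts))) {
    for (c in seq_len(ncol(counts))) {
      if ((r - center[1])^2 + (c - center[2])^2 <= radius^2 + 1e-9) {
        total <- total + counts[r, c]
        n <- n + 1L
      }
    }
  }
  list(total = total, nPixels = n)
}

oracleMeanSd <- function(x) {
  m <- sum(x) / length(x)
  s <- if (length(x) >= 2) sqrt(sum((x - m)^2) / (length(x) - 1)) else NA_real_
  c(mean = m, sd = s)
}

oracleConfusion <- function(disease, testPos) {
  c(tp = sum(disease & testPos), fp = sum(!disease & testPos),
    tn = sum(!disease & !testPos), fn = sum(disease & !testPos))
}

# exhaustive threshold sweep
oracleRoc <- function(hcl, disease) {
  thr <- c(-Inf, sort(unique(hcl)), Inf)
  sens <- spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pos <- hcl >= thr[i]
    sens[i] <- 100 * sum(pos & disease) / sum(disease)
    spec[i] <- 100 * sum(!pos & !disease) / sum(!disease)
  }
  data.frame(threshold = thr, sensitivity = sens, specificity = spec)
}

# tie-corrected Kruskal-Wallis H from first principles
oracleKW <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  rk <- rank(x)
  idx <- rep(seq_along(groups), vapply(groups, length, 1L))
  h <- 12 / (N * (N + 1)) *
    sum(tapply(rk, idx, function(r) length(r) * mean(r)^2)) - 3 * (N + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr == 0) 0 else h / corr
}

# Dunn z-statistics and unadjusted two-sided p-values from first principles
oracleDunnP <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  rk <- rank(x)
  idx <- rep(seq_along(groups), vapply(groups, length, 1L))
  rbar <- tapply(rk, idx, mean)
  n <- vapply(groups, length, 1L)
  ties <- table(x)
  tc <- sum(ties^3 - ties) / (12 * (N - 1))
  k <- length(groups)
  p <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt((N * (N + 1) / 12 - tc) * (1 / n[i] + 1 / n[j]))
    z <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
    p[i, j] <- p[j, i] <- 2 * (1 - pnorm(abs(z)))
  }
  p
}

# random small cohort for property tests
randomCohort <- function(n, seed) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("T%02d", seq_len(n)),
    visual_grade = sample(0:3, n, replace = TRUE),
    hcl = round(runif(n, 0.6, 3), 2),
    diagnosis = sample(c("TTR-CA", "LC-CA", "none"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

tableOneIntervals <- function() {
  GradeIntervals(mean = c(0.98, 1.32, 1.54, 2.40),
                 sd = c(0.11, 0.40, 0.35, 0.76),
                 n = c(77, 19, 7, 67))
}
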