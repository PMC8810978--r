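test_that("visual-rule confusion on the reference cohort gives the printed 2x2", {
  coh <- referenceCohort()
  visual <- ifelse(coh$visual_grade >= 2, "suggestive", "not_suggestive")
  tab <- confusion(coh, visual)
  expect_equal(confusionCounts(tab),
               c(tp = 73, fp = 1, tn = 88, fn = 8))
})

test_that("confusion handles inconclusives and degenerate classifications", {
  coh <- randomCohort(12, seed = 1)
  allPos <- rep("suggestive", 12)
  cc <- confusionCounts(confusion(coh, allPos))
  expect_equal(unname(cc["fn"]), 0)
  expect_equal(unname(cc["tn"]), 0)
  expect_error(confusion(coh, allPos[-1]), "length mismatch")
  # inconclusive counts as negative unless excluded
  cats <- rep(c("suggestive", "inconclusive", "not_suggestive"), each = 4)
  withInc <- confusionCounts(confusion(coh, cats))
  expect_equal(sum(withInc), 12)
  noInc <- confusionCounts(confusion(coh, cats, excludeInconclusive = TRUE))
  expect_equal(sum(noInc), 8)
})

test_that("confusion matches exhaustive manual counting on toy sets", {
  for (s in 1:50) {
    coh <- randomCohort(sample(3:20, 1), seed = 400 + s)
    cats <- sample(c("suggestive", "inconclusive", "not_suggestive"),
                   nrow(coh), replace = TRUE)
    got <- confusionCounts(confusion(coh, cats))
    want <- oracleConfusion(coh$diagnosis == "TTR-CA",
                            cats == "suggestive")
    expect_equal(got, want)
  }
})

test_that("sensSpec reproduces printed performance and guards empty margins", {
  visual <- sensSpec(ConfusionTable(tp = 73, fp = 1, tn = 88, fn = 8))
  expect_equal(roundHalfUp(sensitivity(visual)), 90)
  expect_equal(roundHalfUp(specificity(visual)), 99)
  expect_equal(sensSpec(ConfusionTable(1, 0, 1, 0))@sensitivity, 100)
  expect_equal(sensSpec(ConfusionTable(1, 0, 1, 0))@specificity, 100)
  q13 <- sensSpec(ConfusionTable(tp = 76, fp = 3, tn = 86, fn = 5))
  expect_equal(roundHalfUp(sensitivity(q13), 1), 93.8)
  expect_error(sensSpec(ConfusionTable(0, 2, 3, 0)), "margin")
})

test_that("reporting rounds half away from zero", {
  expect_equal(roundHalfUp(98.876), 99)
  expect_equal(roundHalfUp(89.5), 90)
  expect_equal(roundHalfUp(93.827, 1), 93.8)
  row <- performanceRow(sensSpec(ConfusionTable(73, 1, 88, 8)), 0, "visual")
  expect_equal(row$sensitivity, 90)
  expect_equal(row$specificity, 99)
})

test_that("rocCurve equals the exhaustive threshold sweep", {
  for (s in 1:40) {
    coh <- randomCohort(sample(4:20, 1), seed = 500 + s)
    if (length(unique(coh$diagnosis == "TTR-CA")) < 2) next
    got <- rocPoints(rocCurve(coh))
    want <- oracleRoc(coh$hcl, coh$diagnosis == "TTR-CA")
    expect_equal(got, want)
  }
})

test_that("ROC structure: sentinels, duplicate collapse, monotonicity", {
  coh <- data.frame(patient_id = as.character(1:8),
                    visual_grade = rep(0:3, 2),
                    hcl = c(2, 2, 2, 0.9, 0.9, 1.4, 1.4, 1.4),
                    diagnosis = rep(c("TTR-CA", "none"), each = 4))
  roc <- rocCurve(coh)
  pts <- rocPoints(roc)
  expect_equal(pts$threshold, c(-Inf, 0.9, 1.4, 2, Inf))
  expect_true(all(diff(pts$sensitivity) <= 1e-9))
  expect_true(all(diff(pts$specificity) >= -1e-9))
  # perfectly separated classes admit a (100, 100) operating point
  sep <- data.frame(patient_id = as.character(1:6), visual_grade = 0,
                    hcl = c(2, 2.2, 2.4, 0.8, 0.9, 1.0),
                    diagnosis = rep(c("TTR-CA", "none"), each = 3))
  p2 <- rocPoints(rocCurve(sep))
  expect_true(any(p2$sensitivity == 100 & p2$specificity == 100))
  oneClass <- sep; oneClass$diagnosis <- "TTR-CA"
  expect_error(rocCurve(oneClass), "non-diseased")
})

test_that("optimalCutoff implements both criteria deterministically", {
  # 1.3 and 1.5 share specificity; 1.3 has the higher sensitivity
  coh <- data.frame(
    patient_id = as.character(1:10), visual_grade = 0,
    hcl = c(1.6, 1.6, 1.5, 1.3, 1.3, 1.0, 1.1, 0.9, 0.8, 0.7),
    diagnosis = c(rep("TTR-CA", 6), rep("none", 4)))
  roc <- rocCurve(coh)
  specAt15 <- rocPoints(roc)$specificity[rocPoints(roc)$threshold == 1.5]
  chosen <- optimalCutoff(roc, "max_sens_hold_spec",
                          referenceSpec = specAt15)
  expect_equal(chosenCutoff(chosen), 1.3)
  expect_warning(
    nf <- optimalCutoff(roc, "max_sens_hold_spec", referenceSpec = 101),
    "no feasible")
  expect_true(is.na(chosenCutoff(nf)))
  # Youden picks the dominating vertex
  y <- optimalCutoff(roc, "youden")
  j <- rocPoints(roc)$sensitivity + rocPoints(roc)$specificity - 100
  expect_equal(chosenCutoff(y),
               max(rocPoints(roc)$threshold[j == max(j)]))
})

test_that("Kruskal-Wallis matches hand-ranked arithmetic and the oracle", {
  kw <- kruskalWallisByGrade(list(a = c(1, 2), b = c(3, 4)))
  expect_equal(kwStatistic(kw), 2.4)  # ranks 1,2 vs 3,4 by hand
  expect_equal(unname(meanRanks(kw)), c(1.5, 3.5))
  # all observations tied: H is zero by definition
  flat <- kruskalWallisByGrade(list(a = c(1, 1, 1), b = c(1, 1)))
  expect_equal(kwStatistic(flat), 0)
  expect_error(kruskalWallisByGrade(list(a = 1:3)), "two nonempty groups")
  for (s in 1:30) {
    coh <- randomCohort(sample(6:20, 1), seed = 600 + s)
    groups <- split(coh$hcl, coh$visual_grade)
    groups <- groups[lengths(groups) > 0]
    if (length(groups) < 2) next
    expect_equal(kwStatistic(kruskalWallisByGrade(groups)),
                 oracleKW(groups))
  }
})

test_that("KW statistic is invariant under strictly monotone transforms", {
  coh <- generateCohort(CohortParams(), seed = 23)
  groups <- split(coh$hcl, coh$visual_grade)
  base <- kwStatistic(kruskalWallisByGrade(groups))
  for (f in list(function(x) x^3, exp, function(x) 5 * x - 2)) {
    expect_equal(kwStatistic(kruskalWallisByGrade(lapply(groups, f))), base)
  }
  ranks <- meanRanks(kruskalWallisByGrade(groups))
  expect_true(all(ranks >= 1 & ranks <= nrow(coh)))
})

test_that("Dunn post-hoc matches the pooled-midrank oracle", {
  g <- list(a = c(1.0, 1.2, 1.1), b = c(1.3, 1.5), c = c(2.1, 2.4, 2.2))
  got <- dunnPosthoc(g, adjust = "none")
  want <- oracleDunnP(g)
  expect_equal(unname(got), want, tolerance = 1e-12)
  expect_true(isSymmetric(got))
  expect_true(all(is.na(diag(got))))
  # identical groups are indistinguishable
  same <- dunnPosthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)), adjust = "none")
  expect_gt(same["a", "b"], 0.95)
  # Holm never reports smaller p than unadjusted
  holm <- dunnPosthoc(g, adjust = "holm")
  expect_true(all(holm >= got - 1e-12, na.rm = TRUE))
})

test_that("cohorts at the calibrated parameters separate the grades", {
  coh <- generateCohort(CohortParams(), seed = 29)
  kw <- kruskalWallisByGrade(coh)
  expect_lt(kwPValue(kw), 1e-3)
  p <- posthocP(kw)
  expect_lt(p["0", "3"], 0.05)
  expect_lt(p["1", "3"], 0.05)
})

test_that("the optimized cut-off holds the 1.5-rule operating point at scale", {
  for (s in 1:10) {
    big <- generateCohort(CohortParams(nPerGrade = 100 * c(77, 19, 7, 67)),
                          seed = 900 + s)
    rule15 <- ThresholdRule(1.5, 1.0, "three_category")
    p15 <- sensSpec(confusion(big, classifyThreshold(big$hcl, rule15)))
    roc <- optimalCutoff(rocCurve(big), "max_sens_hold_spec",
                         referenceSpec = specificity(p15))
    cut <- chosenCutoff(roc)
    expect_false(is.na(cut))
    # never worse than the conventional 1.5 rule on either axis
    at <- rocPoints(roc)[rocPoints(roc)$threshold == cut, ]
    expect_gte(at$sensitivity, sensitivity(p15) - 1e-9)
    expect_gte(at$specificity, specificity(p15) - 1e-9)
    # and never beyond the first observed ratio at or above 1.5
    expect_lte(cut, min(big$hcl[big$hcl >= 1.5]))
  }
})
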