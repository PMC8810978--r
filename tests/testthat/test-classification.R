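test_that("ASNC three-category rule follows the stated clauses and precedence", {
  expect_equal(as.character(classifyAsnc(3, 2.40)), "suggestive")
  expect_equal(as.character(classifyAsnc(0, 0.98)), "not_suggestive")
  expect_equal(as.character(classifyAsnc(1, 1.32)), "inconclusive")
  # an H/CL >= 1.5 clause overrides a grade-0 reading
  expect_equal(as.character(classifyAsnc(0, 1.6)), "suggestive")
  # band boundaries: [1.0, 1.5) at full precision, no 1.49/1.50 gap
  expect_equal(as.character(classifyAsnc(0, 1.0)), "inconclusive")
  expect_equal(as.character(classifyAsnc(0, 1.499)), "inconclusive")
  expect_equal(as.character(classifyAsnc(0, 1.5)), "suggestive")
  expect_equal(as.character(classifyAsnc(0, 0.999)), "not_suggestive")
  expect_error(classifyAsnc(4, 1.2), "grade")
  expect_error(classifyAsnc(1, -0.5), "positive")
})

test_that("threshold rules respect boundary inclusion and banding", {
  two <- ThresholdRule(1.3, mode = "two_category")
  expect_equal(as.character(classifyThreshold(1.30, two)), "suggestive")
  expect_equal(as.character(classifyThreshold(1.29, two)), "not_suggestive")
  three <- ThresholdRule(1.3, 1.0, "three_category")
  expect_equal(as.character(classifyThreshold(1.10, three)), "inconclusive")
  expect_equal(as.character(classifyThreshold(0.99, three)), "not_suggestive")
  expect_equal(as.character(classifyThreshold(1.31, three)), "suggestive")
  expect_error(ThresholdRule(1.3, 1.4, "three_category"), "lower < cutoff")
})

test_that("fitGradeIntervals computes n-1 moments and flags degenerate grades", {
  one <- data.frame(patient_id = letters[1:4], visual_grade = 2,
                    hcl = c(1, 2, 3, 4), diagnosis = "TTR-CA")
  iv <- fitGradeIntervals(one)
  expect_equal(unname(gradeMeans(iv)["2"]), 2.5)
  expect_equal(unname(gradeSds(iv)["2"]), 1.2909944, tolerance = 1e-6)
  expect_equal(unname(gradeNs(iv)), c(0, 0, 4, 0))
  # single-record grade: SD undefined, not zero
  single <- data.frame(patient_id = "a", visual_grade = 1, hcl = 1.2,
                       diagnosis = "none")
  expect_true(is.na(gradeSds(fitGradeIntervals(single))["1"]))
  expect_error(fitGradeIntervals(one[0, ]), "empty")
})

test_that("fitGradeIntervals agrees with the brute-force moment oracle", {
  for (s in 1:25) {
    coh <- randomCohort(sample(4:20, 1), seed = 300 + s)
    iv <- fitGradeIntervals(coh)
    for (g in 0:3) {
      x <- coh$hcl[coh$visual_grade == g]
      if (!length(x)) next
      want <- oracleMeanSd(x)
      expect_equal(unname(gradeMeans(iv)[as.character(g)]),
                   unname(want["mean"]))
      if (length(x) >= 2) {
        expect_equal(unname(gradeSds(iv)[as.character(g)]),
                     unname(want["sd"]))
      }
    }
  }
})

test_that("SD-0 cohorts round-trip through interval fitting", {
  p <- CohortParams(nPerGrade = c(0, 9, 0, 0), hclSd = rep(0, 4))
  iv <- fitGradeIntervals(generateCohort(p, seed = 2))
  expect_equal(unname(gradeMeans(iv)["1"]), 1.32)
  expect_equal(unname(gradeSds(iv)["1"]), 0)
})

test_that("interval fitting recovers the generator truth on a large cohort", {
  p <- CohortParams(nPerGrade = c(7700, 1900, 700, 6700))
  iv <- fitGradeIntervals(generateCohort(p, seed = 13))
  for (g in 0:3) {
    target <- hclquant:::truncnormMean(p@hclMean[g + 1], p@hclSd[g + 1],
                                       p@hclFloor)
    se <- p@hclSd[g + 1] / sqrt(p@nPerGrade[g + 1])
    expect_lt(abs(gradeMeans(iv)[[as.character(g)]] - target), 3 * se)
    # and the recovered means sit on the canonical per-grade levels
    expect_lt(abs(gradeMeans(iv)[[as.character(g)]] - p@hclMean[g + 1]), 0.05)
  }
})

test_that("nearest-mean reclassification matches hand-computed cases", {
  iv <- tableOneIntervals()
  expect_equal(reclassifyGrade1(0.95, iv), 0L)   # |0.95-0.98| minimal
  expect_equal(reclassifyGrade1(2.40, iv), 3L)   # distance 0 to grade 3
  # exact tie |1.43-1.32| = |1.43-1.54| breaks to the lower grade
  expect_equal(reclassifyGrade1(1.43, iv), 1L)
  expect_equal(reclassifyGrade1(c(0.95, 1.43, 2.40), iv), c(0L, 1L, 3L))
  bad <- GradeIntervals(mean = c(0.98, NA, 1.54, 2.40), sd = rep(0.1, 4),
                        n = rep(5, 4))
  expect_error(reclassifyGrade1(1.2, bad), "means must be defined")
})

test_that("reclassification is monotone in hcl and fixed on the means", {
  iv <- tableOneIntervals()
  hcl <- seq(0.55, 3.2, by = 0.01)
  g <- reclassifyGrade1(hcl, iv)
  expect_true(all(diff(g) >= 0))
  expect_equal(reclassifyGrade1(unname(gradeMeans(iv)), iv), 0:3)
  # the standardized variant minimizes |hcl - mean| / sd by brute force
  for (x in seq(0.6, 3, by = 0.1)) {
    want <- which.min(abs(x - gradeMeans(iv)) / gradeSds(iv)) - 1L
    expect_equal(reclassifyGrade1(x, iv, method = "standardized"),
                 unname(want))
  }
})

test_that("reclassificationFlow tabulates grade-1 movement", {
  coh <- generateCohort(CohortParams(), seed = 17)
  flow <- reclassificationFlow(coh)
  expect_equal(nrow(flow), 19)
  expect_true(all(flow$new_grade %in% 0:3))
  expect_identical(flow$patient_id,
                   coh$patient_id[coh$visual_grade == 1])
})
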