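test_that("runSimulate writes a seeded cohort and per-grade phantoms", {
  out <- withr::local_tempdir()
  cfg <- defaultRunConfig(seed = 4, output_dir = file.path(out, "run"))
  paths <- runSimulate(cfg)
  expect_true(file.exists(paths$cohort))
  coh <- readCohortCsv(paths$cohort)
  expect_equal(nrow(coh), 170)
  expect_length(paths$images, 4)
  expect_true(all(file.exists(paths$images)))
  expect_true(all(file.exists(paste0(paths$images, ".json"))))
})

test_that("the simulate stage is byte-deterministic for a fixed config", {
  out <- withr::local_tempdir()
  cfgA <- defaultRunConfig(seed = 9, output_dir = file.path(out, "a"))
  cfgB <- defaultRunConfig(seed = 9, output_dir = file.path(out, "b"))
  a <- runSimulate(cfgA)
  b <- runSimulate(cfgB)
  expect_identical(readLines(a$cohort), readLines(b$cohort))
  expect_identical(readLines(a$images[4]), readLines(b$images[4]))
  cfgC <- defaultRunConfig(seed = 10, output_dir = file.path(out, "c"))
  c <- runSimulate(cfgC)
  cohA <- readCohortCsv(a$cohort); cohC <- readCohortCsv(c$cohort)
  expect_false(identical(cohA$hcl, cohC$hcl))
  expect_identical(table(cohA$visual_grade), table(cohC$visual_grade))
})

test_that("runEvaluate produces the full report set on a simulated cohort", {
  out <- withr::local_tempdir()
  cfg <- defaultRunConfig(seed = 2, output_dir = file.path(out, "run"))
  runSimulate(cfg)
  res <- runEvaluate(cfg)
  expect_true(all(file.exists(file.path(
    cfg$output_dir,
    c("performance.csv", "reclassification.csv", "intervals.json",
      "kruskal_wallis.json", "roc.csv")))))
  perf <- res$performance
  # visual + ASNC + 4 configured threshold rules
  expect_equal(nrow(perf), 6)
  expect_true(all(perf$sensitivity >= 0 & perf$sensitivity <= 100))
  expect_equal(nrow(res$flow), 19)
  # intervals JSON round-trips
  iv <- readGradeIntervals(file.path(cfg$output_dir, "intervals.json"))
  expect_equal(gradeMeans(iv), gradeMeans(res$intervals))
})

test_that("grade-level cohorts evaluate the visual rule only", {
  out <- withr::local_tempdir()
  csv <- file.path(out, "ref.csv")
  writeCohortCsv(referenceCohort(), csv)
  cfg <- defaultRunConfig(seed = 1, output_dir = file.path(out, "run"))
  res <- runEvaluate(cfg, cohortCsv = csv)
  perf <- res$performance
  expect_equal(nrow(perf), 1)
  expect_equal(perf$sensitivity, 90)
  expect_equal(perf$specificity, 99)
})

test_that("cohort CSV io validates rows and round-trips", {
  out <- withr::local_tempdir()
  coh <- generateCohort(CohortParams(), seed = 6)
  csv <- file.path(out, "cohort.csv")
  writeCohortCsv(coh, csv)
  back <- readCohortCsv(csv)
  expect_equal(back$visual_grade, coh$visual_grade)
  expect_equal(back$hcl, coh$hcl, tolerance = 1e-12)
  bad <- coh
  bad$visual_grade[5] <- 7
  badCsv <- file.path(out, "bad.csv")
  utils::write.csv(bad, badCsv, row.names = FALSE)
  expect_error(readCohortCsv(badCsv), "row\\(s\\) 5")
  empty <- coh[0, ]
  emptyCsv <- file.path(out, "empty.csv")
  utils::write.csv(empty, emptyCsv, row.names = FALSE)
  expect_error(runEvaluate(defaultRunConfig(1, file.path(out, "r")),
                           cohortCsv = emptyCsv),
               "empty cohort")
})

test_that("planar images round-trip through the text format", {
  out <- withr::local_tempdir()
  img <- generatePhantom(2, PhantomParams(imageShape = c(48, 48),
                                          heartCenter = c(24, 14),
                                          heartRadius = 6), seed = 3)
  path <- file.path(out, "img.csv")
  writePlanarImage(img, path)
  back <- readPlanarImage(path)
  expect_equal(imageCounts(back), imageCounts(img))
  expect_equal(back@projection, "anterior")
  png <- file.path(out, "img.png")
  writePhantomPng(img, png)
  expect_true(file.size(png) > 0)
})

test_that("JSON run configs are validated and merged over defaults", {
  out <- withr::local_tempdir()
  cfgPath <- file.path(out, "cfg.json")
  writeLines('{
    "seed": 7,
    "output_dir": "runout",
    "phantom": {"image_shape": [64, 64], "heart_center": [32, 18],
                 "heart_radius": 8},
    "cohort": {"n_per_grade": [10, 10, 10, 10]}
  }', cfgPath)
  cfg <- readRunConfig(cfgPath)
  expect_equal(cfg$seed, 7L)
  expect_equal(cfg$phantomParams@imageShape, c(64, 64))
  expect_equal(cfg$cohortParams@nPerGrade, rep(10, 4))
  # defaults retained where the file is silent
  expect_length(cfg$thresholdRules, 4)
  writeLines('{"seed": 1, "bogus": 2}', cfgPath)
  expect_error(readRunConfig(cfgPath), "unknown run-config field")
})

test_that("classifyCohort appends category and reclassified_grade", {
  coh <- generateCohort(CohortParams(), seed = 15)
  cls <- classifyCohort(coh)
  expect_true(all(c("category", "reclassified_grade") %in% names(cls)))
  expect_true(all(cls$category %in%
                    c("suggestive", "inconclusive", "not_suggestive")))
  moved <- cls$visual_grade == 1
  expect_true(all(cls$reclassified_grade[!moved] ==
                    cls$visual_grade[!moved]))
  # threshold-rule variant
  cls13 <- classifyCohort(coh, rule = ThresholdRule(1.3, 1, "three_category"))
  expect_equal(as.character(cls13$category),
               as.character(classifyThreshold(
                 coh$hcl, ThresholdRule(1.3, 1, "three_category"))))
})
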