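test_that("subject splits have the protocol sizes and never overlap", {
  sp <- splitBySubject(sprintf("S%02d", 1:44), fraction = 0.75, folds = 6)
  expect_length(sp, 6L)
  for (s in sp) {
    expect_length(s@trainIds, 33L)
    expect_length(s@testIds, 11L)
    expect_length(intersect(s@trainIds, s@testIds), 0L)
    expect_setequal(c(s@trainIds, s@testIds), sprintf("S%02d", 1:44))
  }
  two <- splitBySubject(c("a", "b"), fraction = 0.5, folds = 3)
  expect_true(all(vapply(two, function(s)
    length(s@trainIds) == 1 && length(s@testIds) == 1, logical(1))))
  expect_error(splitBySubject("only"), class = "InvalidSplit")
  expect_error(splitBySubject(c("a", "b"), fraction = 0.01),
               class = "InvalidSplit")
})

test_that("standardization fits, transforms, and detects constants", {
  tab <- syntheticSelectionTable(nSubjects = 4, rowsPerSubject = 25)
  out <- standardizeFeatures(tab)
  X <- as.matrix(featureData(out$table)[, featureNames(tab)])
  expect_true(all(abs(colMeans(X)) < 1e-9))
  expect_true(all(abs(apply(X, 2, sd) - 1) < 1e-9))
  # out-of-sample transform need not be centred
  tab2 <- syntheticSelectionTable(nSubjects = 4, rowsPerSubject = 25,
                                  seed = 9L)
  out2 <- standardizeFeatures(tab2, params = out$params)
  X2 <- as.matrix(featureData(out2$table)[, featureNames(tab)])
  expect_gt(max(abs(colMeans(X2))), 1e-6)

  const <- tab
  const@table$f1 <- 1
  expect_error(standardizeFeatures(const), class = "DegenerateFeature")
})

test_that("training on separable data is perfect, deterministic, and
           generalizes to held-out subjects", {
  tab <- syntheticSelectionTable(nSubjects = 8, rowsPerSubject = 40,
                                 separationSd = 6, seed = 3L)
  sp <- splitBySubject(unique(featureData(tab)$subject), 0.75, 1, seed = 1)[[1]]
  grid <- 10^seq(-2, 2, length.out = 5)
  est <- trainEstimator(tab, split = sp, grid = grid, seed = 1L)
  est2 <- trainEstimator(tab, split = sp, grid = grid, seed = 1L)
  expect_identical(est@weights, est2@weights)
  expect_identical(est@bias, est2@bias)
  expect_setequal(est@metadata$subjects, sp@trainIds)

  predict_rows <- function(est, df) {
    X <- scale(as.matrix(df[, est@featureNames]), est@center, est@scale)
    as.numeric(drop(X %*% est@weights + est@bias) > 0)
  }
  dtr <- featureData(tab)[featureData(tab)$subject %in% sp@trainIds, ]
  expect_equal(mean(predict_rows(est, dtr) == dtr$label), 1.0)
  dte <- featureData(tab)[featureData(tab)$subject %in% sp@testIds, ]
  expect_gte(mean(predict_rows(est, dte) == dte$label), 0.95)
})

test_that("single-class training data raises DegenerateLabels", {
  tab <- syntheticSelectionTable(nSubjects = 4, rowsPerSubject = 20)
  tab@table$label <- 1
  expect_error(trainEstimator(tab), class = "DegenerateLabels")
})

test_that("predicted masks live on the input grid and respect geometry", {
  cohort <- generateCohort(5, seed = 11L)
  vols <- setNames(lapply(cohort[1:4], `[[`, "volume"),
                   sapply(cohort[1:4], `[[`, "subjectId"))
  masks <- lapply(cohort[1:4], `[[`, "truth")
  tab <- buildFeatureTable(vols, masks)
  est <- trainEstimator(tab, grid = 10^seq(-1, 2, length.out = 4),
                        seed = 2L, maxRows = 8000L)
  ph <- cohort[[5]]
  pred <- predictMask(est, ph$volume)
  expect_s4_class(pred, "BinaryMask")
  expect_identical(dim(imageData(pred)), dim(imageData(ph$volume)))
  expect_gt(jaccardIndex(pred, ph$truth), 0.5)

  # missing features and grid mismatches are reported by name
  fv <- extractFeatures(ph$volume, c("hci", "nd", "card", "neig"))
  expect_error(predictMask(est, ph$volume, fv[c("hci", "nd")]),
               class = "MissingFeature")
  bad <- fv
  bad$neig <- bad$neig[1:10, , ]
  expect_error(predictMask(est, ph$volume, bad), class = "AlignmentError")
})

test_that("a ventricle-free head yields a near-empty mask", {
  cohort <- generateCohort(4, seed = 21L)
  vols <- setNames(lapply(cohort, `[[`, "volume"),
                   sapply(cohort, `[[`, "subjectId"))
  masks <- lapply(cohort, `[[`, "truth")
  est <- trainEstimator(buildFeatureTable(vols, masks),
                        grid = 10^seq(-1, 2, length.out = 4), seed = 3L,
                        maxRows = 8000L)
  # shrinking the ventricle ellipsoids below the voxel size removes the
  # CSF class entirely while keeping the acquisition geometry
  ph0 <- generatePhantom(phantomSpec(ventricleScale = 0.05, seed = 61L))
  expect_identical(sum(imageData(ph0$truth)), 0L)
  pred <- predictMask(est, ph0$volume)
  expect_lt(mean(imageData(pred)), 0.01)
})

test_that("estimators survive a JSON round trip bit-for-bit", {
  tab <- syntheticSelectionTable(nSubjects = 4, rowsPerSubject = 30)
  est <- trainEstimator(tab, grid = c(0.1, 1, 10), seed = 4L)
  f <- withr::local_tempfile(fileext = ".json")
  writeEstimator(est, f)
  back <- readEstimator(f)
  expect_identical(back@featureNames, est@featureNames)
  expect_equal(back@weights, est@weights)
  expect_equal(back@bias, est@bias)
  expect_equal(back@center, est@center)
  expect_equal(back@scale, est@scale)
})
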