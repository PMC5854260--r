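test_that("normalized distance is zero at the isocenter and Euclidean", {
  vol <- makeVolume(array(0, c(8, 8, 8)))  # origin at voxel (0,0,0)
  nd <- normalizedDistance(vol)
  expect_equal(nd[1, 1, 1], 0)
  expect_equal(nd[4, 5, 1], 5)             # 3-4-5 triple
  expect_true(all(nd >= 0))
})

test_that("normalized distance is geometric: invariant to intensities and
           symmetric about the isocenter", {
  set.seed(6)
  A <- array(rnorm(9^3), c(9, 9, 9))
  aff <- diag(4)
  aff[1:3, 4] <- -4                        # isocenter at grid centre
  v1 <- new("VolumeImage", data = A, affine = aff, spacing = c(1, 1, 1))
  v2 <- new("VolumeImage", data = A * 100 + 7, affine = aff,
            spacing = c(1, 1, 1))
  expect_identical(normalizedDistance(v1), normalizedDistance(v2))
  nd <- normalizedDistance(v1)
  expect_equal(nd, nd[9:1, , ])            # mirror symmetry
  # brute force check
  idx <- ventvol:::voxelIndexGrid(c(9, 9, 9))
  brute <- sqrt(rowSums((idx - 4)^2))
  expect_equal(as.vector(nd), brute)
})

test_that("SCV may lie outside the grid and distances stay finite", {
  aff <- diag(4)
  aff[1:3, 4] <- c(100, 0, 0)              # origin far outside
  vol <- new("VolumeImage", data = array(0, c(5, 5, 5)), affine = aff,
             spacing = c(1, 1, 1))
  nd <- normalizedDistance(vol)
  expect_true(all(is.finite(nd)) && all(nd > 0))
})

test_that("cardinality assigns consecutive block indices", {
  vol <- makeVolume(array(0, c(8, 8, 8)))
  card <- cardinalityFeature(vol, c(4, 4, 4))
  expect_equal(card[1, 1, 1], 1)           # all floors zero, +1
  expect_setequal(unique(as.vector(card)), 1:8)
  # each block is a 4^3 axis-aligned box
  for (b in 1:8) expect_equal(sum(card == b), 64)
  # consecutive along x
  expect_equal(card[5, 1, 1] - card[4, 1, 1], 1)
  # full-axis dividers collapse to one block; oversize dividers clamp
  expect_true(all(cardinalityFeature(vol, c(8, 8, 8)) == 1))
  expect_true(all(cardinalityFeature(vol, c(99, 99, 99)) == 1))
  # partition property on an uneven grid
  vol2 <- makeVolume(array(0, c(10, 7, 5)))
  card2 <- cardinalityFeature(vol2, c(4, 4, 4))
  expect_identical(sum(table(card2)), as.integer(10 * 7 * 5))
})

test_that("neighboring matches the brute-force oracle on random volumes", {
  set.seed(13)
  for (i in 1:12) {
    A <- array(rnorm(6^3), c(6, 6, 6))
    vol <- makeVolume(A)
    expect_identical(neighboringFeature(vol), neighboringOracle(A))
  }
})

test_that("neighboring attains 26 at a maximal-contrast interior voxel and
           0 on constant fields", {
  A <- array(0, c(5, 5, 5))
  A[3, 3, 3] <- 100
  vol <- makeVolume(A)
  neig <- neighboringFeature(vol)
  expect_equal(neig[3, 3, 3], 26)
  expect_true(all(neig >= 0 & neig <= 26))
  const <- makeVolume(array(4, c(5, 5, 5)))
  expect_true(all(neighboringFeature(const) == 0))
})

test_that("candidate pool has the documented structure", {
  const <- makeVolume(array(3, c(7, 7, 7)))
  pool <- candidatePool(const)
  expect_named(pool, c("intensity", "laplacian", "log_s1", "log_s2",
                       "log_s3"))
  expect_identical(pool$intensity, imageData(const))
  expect_true(all(abs(pool$laplacian) < 1e-12))
  expect_true(all(abs(pool$log_s2) < 1e-12))

  A <- array(0, c(7, 7, 7))
  A[4, 4, 4] <- 10
  lap <- candidatePool(makeVolume(A))$laplacian
  expect_lt(lap[4, 4, 4], 0)
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)))
    expect_gt(lap[4 + o[1], 4 + o[2], 4 + o[3]], 0)
})

test_that("the feature table has one row per voxel and conserves labels", {
  ph1 <- generatePhantom(phantomSpec(dim = c(14, 12, 10), seed = 1L))
  ph2 <- generatePhantom(phantomSpec(dim = c(14, 12, 10), seed = 2L))
  vols <- list(A = ph1$volume, B = ph2$volume)
  masks <- list(ph1$truth, ph2$truth)
  tab <- buildFeatureTable(vols, masks, features = c("nd", "card"))
  df <- featureData(tab)
  expect_identical(nrow(df), 2L * 14L * 12L * 10L)
  expect_setequal(names(df), c("subject", "x", "y", "z", "nd", "card",
                               "label"))
  expect_equal(sum(df$label),
               sum(imageData(ph1$truth)) + sum(imageData(ph2$truth)))
  expect_setequal(unique(df$subject), c("A", "B"))
  # no labels when masks absent
  tab0 <- buildFeatureTable(vols["A"], features = c("nd"))
  expect_true(all(featureData(tab0)$label == 0))
})

test_that("misaligned masks raise AlignmentError", {
  ph <- generatePhantom(phantomSpec(dim = c(12, 12, 12), seed = 1L))
  small <- makeMask(array(FALSE, c(11, 12, 12)))
  expect_error(buildFeatureTable(list(S = ph$volume), list(small)),
               class = "AlignmentError")
})

test_that("feature table CSV export uses the documented column order", {
  ph <- generatePhantom(phantomSpec(dim = c(10, 10, 10), seed = 1L))
  tab <- buildFeatureTable(list(S = ph$volume), list(ph$truth),
                           features = c("nd", "neig"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(tab, f)
  expect_identical(names(read.csv(f)), c("nd", "neig", "label", "subject"))
})
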