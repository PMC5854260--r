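test_that("NIfTI round trip preserves data, spacing and affine", {
  ph <- generatePhantom(phantomSpec(dim = c(12, 14, 10), seed = 3L))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(ph$volume, f)
  back <- loadVolume(f)
  expect_identical(dim(imageData(back)), dim(imageData(ph$volume)))
  expect_identical(imageData(back), imageData(ph$volume))
  expect_equal(imageSpacing(back), imageSpacing(ph$volume))
  expect_equal(imageAffine(back), imageAffine(ph$volume),
               ignore_attr = TRUE)

  fm <- withr::local_tempfile(fileext = ".nii.gz")
  writeMask(ph$truth, fm)
  backMask <- loadMask(fm, reference = back)
  expect_identical(imageData(backMask), imageData(ph$truth))
})

test_that("loading rejects missing files and 4D payloads", {
  expect_error(loadVolume(file.path(tempdir(), "nope.nii")),
               class = "ventvolError")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(6, 6, 6, 2))), f)
  expect_error(loadVolume(f), class = "UnsupportedImage")
})

test_that("voxel volume is the spacing product and scales multiplicatively", {
  expect_equal(round(voxelVolume(c(0.41, 0.41, 1.00)), 2), 0.17)
  expect_equal(round(voxelVolume(c(0.39, 0.39, 4.99)), 2), 0.76)
  expect_identical(voxelVolume(c(1, 1, 1)), 1)
  base <- voxelVolume(c(0.7, 1.1, 2.3))
  for (k in c(0.5, 2, 3))
    expect_equal(voxelVolume(c(0.7 * k, 1.1, 2.3)), k * base)
  expect_error(voxelVolume(c(1, -1, 1)), class = "InvalidGeometry")
  expect_error(voxelVolume(c(1, 1)), class = "InvalidGeometry")
})

test_that("resampling at the native grid is the identity", {
  vol <- makeVolume(array(rnorm(4 * 5 * 6), c(4, 5, 6)))
  out <- resampleIsotropic(vol, 1)
  expect_identical(imageData(out), imageData(vol))
})

test_that("resampling halves/doubles grids and preserves constants", {
  vol <- makeVolume(array(rnorm(16^3), c(16, 16, 16)),
                    spacing = c(0.5, 0.5, 0.5))
  out <- resampleIsotropic(vol, 1)
  expect_identical(dim(imageData(out)), c(8L, 8L, 8L))
  expect_equal(imageSpacing(out), c(1, 1, 1))
  # intensity range not expanded by linear interpolation
  expect_gte(min(imageData(out)), min(imageData(vol)))
  expect_lte(max(imageData(out)), max(imageData(vol)))

  cvol <- makeVolume(array(7.5, c(9, 9, 9)), spacing = c(0.7, 0.7, 0.7))
  expect_true(all(abs(imageData(resampleIsotropic(cvol, 1)) - 7.5) < 1e-9))
  expect_error(resampleIsotropic(vol, -1), class = "InvalidGeometry")
})

test_that("resampling preserves world positions of voxel centres", {
  vol <- makeVolume(array(rnorm(10^3), c(10, 10, 10)),
                    spacing = c(0.5, 0.5, 0.5), origin = c(-3, 2, 7))
  out <- resampleIsotropic(vol, 1)
  # first voxel centre is anchored
  expect_equal(imageAffine(out)[1:3, 4], imageAffine(vol)[1:3, 4])
  # a voxel centre of the output maps to the same world point under both
  # geometries' index conventions
  w <- imageAffine(out) %*% c(3, 4, 2, 1)
  src <- solve(imageAffine(vol)) %*% w
  expect_equal(drop(src[1:3]), c(6, 8, 4))
})

test_that("mask resampling is nearest-neighbour, binary, volume-preserving", {
  # solid cube occupying half the FOV at 0.5 mm
  d <- c(20, 20, 20)
  cube <- array(FALSE, d)
  cube[1:10, , ] <- TRUE
  mask <- makeMask(cube, spacing = c(0.5, 0.5, 0.5))
  out <- resampleMask(mask, 1)
  expect_true(is.logical(imageData(out)))
  v0 <- maskVolume(mask)
  v1 <- maskVolume(out)
  # preserved within one voxel layer of the cube surface (10x10 mm face)
  expect_lt(abs(v1 - v0), 100 + 1e-9)

  ones <- makeMask(array(TRUE, c(8, 8, 8)), spacing = c(0.5, 0.5, 0.5))
  expect_true(all(imageData(resampleMask(ones, 1))))
  none <- makeMask(array(FALSE, c(8, 8, 8)), spacing = c(0.5, 0.5, 0.5))
  expect_false(any(imageData(resampleMask(none, 1))))
})

test_that("smooth masks keep their volume within 5% across resampling", {
  ph <- generatePhantom(phantomSpec(spacing = c(0.8, 0.8, 0.8),
                                    dim = c(56, 64, 56), noiseSd = 0,
                                    ventricleScale = 1.8, seed = 5L))
  m <- ph$truth
  expect_gte(maskVolume(m), 1000)
  out <- resampleMask(m, 1)
  expect_lt(abs(maskVolume(out) - maskVolume(m)) / maskVolume(m), 0.05)
})

test_that("world coordinates follow the affine", {
  vol <- makeVolume(array(0, c(3, 3, 3)), spacing = c(2, 2, 2),
                    origin = c(1, -1, 0))
  w <- worldCoordinates(vol)
  expect_equal(w[1, ], c(1, -1, 0))
  expect_equal(w[2, ], c(3, -1, 0))  # next voxel along x: +2 mm
})
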