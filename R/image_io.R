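## NIfTI input/output and isotropic resampling.
##
## World geometry follows the NIfTI convention: a voxel with 0-based index
## (i, j, k) sits at world position affine %*% c(i, j, k, 1) in mm, and the
## world origin is the scanner isocenter.

#' Load a 3D NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file into a [VolumeImage-class]. The affine and
#' spacing are taken from the header; header scale/slope rescaling is
#' applied by the reader but no further intensity transformation occurs.
#'
#' @param path path to an existing NIfTI file with a 3D scalar payload.
#' @return a [VolumeImage-class].
#' @examples
#' vol <- generatePhantom(phantomSpec(dim = c(16, 16, 16)))$volume
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(vol, f)
#' identical(imageData(loadVolume(f)), imageData(vol))
#' @export
loadVolume <- function(path) {
  if (!file.exists(path))
    ventvolError(paste("file not found:", path), "IOError")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stopUnsupportedImage(sprintf(
      "expected a 3D scalar volume, got %d dimensions (%s)",
      length(d), paste(d, collapse = "x")))
  aff <- unclass(RNifti::xform(img))
  if (abs(det(aff)) < 1e-12)
    stopInvalidGeometry("image affine is not invertible")
  spacing <- RNifti::pixdim(img)[1:3]
  newVolume(array(as.numeric(img), dim = d), matrix(aff, 4, 4), spacing)
}

#' Load a binary NIfTI mask
#'
#' @param path path to a NIfTI file; any non-zero voxel becomes TRUE.
#' @param reference optional [VolumeImage-class] whose grid the mask must
#'   match (an `AlignmentError` is raised otherwise).
#' @return a [BinaryMask-class].
#' @export
loadMask <- function(path, reference = NULL) {
  vol <- loadVolume(path)
  if (!is.null(reference) &&
      !identical(dim(vol@data), dim(reference@data)))
    stopAlignmentError("mask grid does not match the reference volume grid")
  newMask(vol@data != 0, vol@affine, vol@spacing)
}

#' Write a volume or mask to NIfTI
#'
#' @param vol a [VolumeImage-class].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return the path, invisibly.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@data)
  img <- RNifti::`sform<-`(img, structure(vol@affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname writeVolume
#' @param mask a [BinaryMask-class].
#' @export
writeMask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask@data), dim = dim(mask@data)))
  img <- RNifti::`sform<-`(img, structure(mask@affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Physical volume of one voxel
#'
#' The voxel volume is the product of the in-plane resolution factors and
#' the slice thickness.
#'
#' @param spacing numeric length-3 voxel edge lengths (sx, sy, sz) in mm.
#' @return the voxel volume sx * sy * sz in mm^3.
#' @examples
#' voxelVolume(c(0.41, 0.41, 1.00))  # 0.1681 mm^3
#' @export
voxelVolume <- function(spacing) {
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopInvalidGeometry("spacing must be three positive finite values")
  prod(spacing)
}

#' World coordinates of every voxel centre
#'
#' @param vol a [VolumeImage-class] or [BinaryMask-class].
#' @return an n-voxel x 3 matrix of world positions (mm), rows in array
#'   (column-major) order.
#' @export
worldCoordinates <- function(vol) {
  d <- dim(vol@data)
  idx <- voxelIndexGrid(d)
  t(vol@affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
}

## 0-based index grid in array order, n x 3
voxelIndexGrid <- function(d) {
  cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
}

## Trilinear sampling of `data` at fractional 0-based coordinates (n x 3).
## Coordinates are clamped to the grid (edge extension).
trilinearSample <- function(data, coords) {
  d <- dim(data)
  cl <- pmin(pmax(coords, 0), matrix(d - 1L, nrow(coords), 3, byrow = TRUE))
  f0 <- floor(cl)
  fr <- cl - f0
  f0 <- f0 + 1L                       # to 1-based
  f1 <- pmin(f0 + 1L, matrix(d, nrow(coords), 3, byrow = TRUE))
  at <- function(ix, iy, iz)
    data[cbind(ix, iy, iz)]
  w <- function(a, b, c)
    (if (a) fr[, 1] else 1 - fr[, 1]) *
    (if (b) fr[, 2] else 1 - fr[, 2]) *
    (if (c) fr[, 3] else 1 - fr[, 3])
  out <- numeric(nrow(coords))
  for (a in 0:1) for (b in 0:1) for (c in 0:1) {
    ww <- w(a == 1, b == 1, c == 1)
    nz <- ww != 0
    if (any(nz))
      out[nz] <- out[nz] + ww[nz] *
        at(if (a) f1[nz, 1] else f0[nz, 1],
           if (b) f1[nz, 2] else f0[nz, 2],
           if (c) f1[nz, 3] else f0[nz, 3])
  }
  out
}

nearestSample <- function(data, coords) {
  d <- dim(data)
  cl <- pmin(pmax(round(coords), 0),
             matrix(d - 1L, nrow(coords), 3, byrow = TRUE)) + 1L
  data[cl]
}

resampleGeometry <- function(vol, target) {
  d <- dim(vol@data)
  newDim <- as.integer(ceiling(d * vol@spacing / target))
  if (any(newDim < 1L))
    stopInvalidGeometry("resampling target produces an empty grid")
  ## direction columns rescaled to the target spacing; the world position of
  ## the first voxel centre is preserved
  dirs <- vol@affine[1:3, 1:3]
  unit <- sweep(dirs, 2, vol@spacing, "/")
  newAff <- vol@affine
  newAff[1:3, 1:3] <- unit * target
  list(dim = newDim, affine = newAff)
}

#' Resample a volume to an isotropic grid
#'
#' The output grid has `ceiling(extent_mm / target)` voxels per axis and is
#' anchored at the world position of the original first voxel centre. For
#' each output voxel centre the world position is mapped back through the
#' input affine and the intensity interpolated there.
#'
#' @param vol a [VolumeImage-class].
#' @param target isotropic voxel size in mm (> 0).
#' @param interpolation `"linear"` (default, intensities) or `"nearest"`.
#' @return a [VolumeImage-class] with spacing `c(target, target, target)`.
#' @export
resampleIsotropic <- function(vol, target = 1,
                              interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (!is.finite(target) || target <= 0)
    stopInvalidGeometry("target spacing must be > 0")
  if (all(abs(vol@spacing - target) < 1e-9))
    return(vol)                        # grid-aligned identity
  g <- resampleGeometry(vol, target)
  idx <- voxelIndexGrid(g$dim)
  world <- g$affine %*% rbind(t(idx), 1)
  src <- t(solve(vol@affine) %*% world)[, 1:3, drop = FALSE]
  vals <- switch(interpolation,
                 linear = trilinearSample(vol@data, src),
                 nearest = nearestSample(vol@data, src))
  newVolume(array(vals, dim = g$dim), g$affine, rep(target, 3))
}

#' Resample a binary mask to an isotropic grid
#'
#' Nearest-neighbour interpolation, preserving strict binarity.
#'
#' @param mask a [BinaryMask-class].
#' @param target isotropic voxel size in mm.
#' @return a [BinaryMask-class].
#' @export
resampleMask <- function(mask, target = 1) {
  asVol <- newVolume(array(as.numeric(mask@data), dim = dim(mask@data)),
                     mask@affine, mask@spacing)
  out <- resampleIsotropic(asVol, target, interpolation = "nearest")
  newMask(out@data != 0, out@affine, out@spacing)
}
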