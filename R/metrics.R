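## Volume and overlap metrics for comparing segmentations.

#' Physical volume of a mask
#'
#' @param mask a [BinaryMask-class].
#' @return positive voxel count times voxel volume, in mm^3.
#' @export
maskVolume <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  sum(mask@data) * voxelVolume(mask@spacing)
}

#' Signed volume difference
#'
#' @param manual,auto volumes in mm^3.
#' @return `manual - auto` (mm^3, signed).
#' @examples
#' volumeDifference(5065.09, 4664.51)  # 400.58
#' @export
volumeDifference <- function(manual, auto) manual - auto

#' Jaccard overlap of two masks
#'
#' Intersection over union. Two empty masks agree perfectly and score 1.
#'
#' @param a,b grid-aligned [BinaryMask-class] objects.
#' @return a ratio in [0, 1].
#' @export
jaccardIndex <- function(a, b) {
  stopifnot(is(a, "BinaryMask"), is(b, "BinaryMask"))
  if (!identical(dim(a@data), dim(b@data)))
    stopAlignmentError("masks are on different grids")
  uni <- sum(a@data | b@data)
  if (uni == 0) return(1.0)
  sum(a@data & b@data) / uni
}

#' Compare a manual and an automatic segmentation
#'
#' @param manual,auto grid-aligned [BinaryMask-class] objects.
#' @return one-row data.frame with manual and automatic volumes (mm^3),
#'   their signed difference and the Jaccard index.
#' @export
compareSegmentations <- function(manual, auto) {
  mv <- maskVolume(manual)
  av <- maskVolume(auto)
  data.frame(manualVolume = mv, autoVolume = av,
             difference = volumeDifference(mv, av),
             jaccard = jaccardIndex(manual, auto))
}
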