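#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' VolumeImage: a 3D scalar MR volume with world geometry
#'
#' Container for a single-channel 3D image together with the 4x4 affine
#' mapping 0-based voxel indices to world coordinates in millimetres
#' (voxel-centre convention, as in the NIfTI standard) and the voxel
#' spacing along each axis.
#'
#' @slot data 3D numeric array of finite intensities (arbitrary MR units).
#' @slot affine invertible 4x4 voxel-index to world-mm transform.
#' @slot spacing numeric length-3, voxel edge lengths in mm, all > 0.
#'
#' @seealso [loadVolume()], [resampleIsotropic()], [BinaryMask-class]
#' @export
setClass("VolumeImage",
  representation(data = "array", affine = "matrix", spacing = "numeric"))

setValidity("VolumeImage", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a rank-3 array")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "all intensities must be finite")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  else if (abs(det(object@affine)) < 1e-12)
    msg <- c(msg, "affine must be invertible")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive finite values")
  if (length(msg)) msg else TRUE
})

#' BinaryMask: a boolean volume aligned to a VolumeImage grid
#'
#' @slot data 3D logical array.
#' @slot affine 4x4 voxel-index to world-mm transform inherited from the
#'   paired intensity volume.
#' @slot spacing voxel edge lengths in mm.
#'
#' @seealso [maskVolume()], [jaccardIndex()]
#' @export
setClass("BinaryMask",
  representation(data = "array", affine = "matrix", spacing = "numeric"))

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a rank-3 array")
  if (!is.logical(object@data) || anyNA(object@data))
    msg <- c(msg, "mask values must be logical and non-missing")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive values")
  if (length(msg)) msg else TRUE
})

#' HistogramEnvelope: smoothed intensity histogram with its stretch map
#'
#' The envelope is a Gaussian-smoothed version of the raw intensity
#' histogram. The stretch map is the invertible affine transform taking the
#' observed intensity range onto the standard [0, 255] axis on which peak
#' detection operates; its inverse maps detected positions back to
#' intensities.
#'
#' @slot binCenters strictly increasing intensity values, one per bin.
#' @slot envelope smoothed counts, same length as binCenters, all >= 0.
#' @slot stretch numeric c(scale, offset): stretched = scale * x + offset.
#'
#' @seealso [computeEnvelope()], [detectBoundaries()]
#' @export
setClass("HistogramEnvelope",
  representation(binCenters = "numeric", envelope = "numeric",
                 stretch = "numeric"))

setValidity("HistogramEnvelope", function(object) {
  msg <- character()
  if (length(object@binCenters) != length(object@envelope))
    msg <- c(msg, "binCenters and envelope must have equal length")
  if (any(diff(object@binCenters) <= 0))
    msg <- c(msg, "binCenters must be strictly increasing")
  if (any(object@envelope < 0))
    msg <- c(msg, "envelope values must be non-negative")
  if (length(object@stretch) != 2L || object@stretch[1] == 0)
    msg <- c(msg, "stretch must be c(scale, offset) with scale != 0")
  if (length(msg)) msg else TRUE
})

#' ParcellationBoundaries: four intensity cut points
#'
#' The cut points p1 < p2 < p3 < p4 returned by histogram parcellation.
#' Voxels are labelled R1 (I < p1), R2 (p1 <= I < p2), R3 (p2 <= I < p3)
#' and R4 (p3 <= I).
#'
#' @slot cuts sorted numeric vector of length 4.
#'
#' @seealso [detectBoundaries()], [assignLabels()]
#' @export
setClass("ParcellationBoundaries", representation(cuts = "numeric"))

setValidity("ParcellationBoundaries", function(object) {
  if (length(object@cuts) != 4L) return("cuts must have length 4")
  if (any(!is.finite(object@cuts))) return("cuts must be finite")
  if (any(diff(object@cuts) <= 0)) return("cuts must satisfy p1 < p2 < p3 < p4")
  TRUE
})

#' FeatureTable: per-voxel feature rows for training or inference
#'
#' One row per voxel. The underlying data frame holds the subject
#' identifier, the 0-based voxel grid coordinates (retained so predicted
#' labels can be reassembled into masks), one column per feature, and -
#' for supervised tables - a binary label column.
#'
#' @slot table data.frame with columns subject, x, y, z, the features, and
#'   optionally label.
#' @slot featureNames ordered character vector naming the feature columns.
#'
#' @seealso [buildFeatureTable()], [strongForceSelect()], [trainEstimator()]
#' @export
setClass("FeatureTable",
  representation(table = "data.frame", featureNames = "character"))

setValidity("FeatureTable", function(object) {
  msg <- character()
  needed <- c("subject", "x", "y", "z", object@featureNames)
  missing <- setdiff(needed, names(object@table))
  if (length(missing))
    msg <- c(msg, paste("missing columns:", paste(missing, collapse = ", ")))
  if (anyNA(object@table))
    msg <- c(msg, "feature table must not contain missing values")
  if ("label" %in% names(object@table) &&
      !all(object@table$label %in% c(0, 1)))
    msg <- c(msg, "label column must be binary 0/1")
  if (length(msg)) msg else TRUE
})

#' FeatureSelectionReport: result of the exhaustive subset search
#'
#' @slot participants list of character vectors, the evaluated feature
#'   subsets.
#' @slot scores mean cross-validated accuracy per subset, in [0, 1].
#' @slot regularization best regularization strength per subset.
#' @slot selected the best-scoring subset (ties broken toward fewer
#'   features).
#' @slot grid the regularization grid searched.
#'
#' @seealso [strongForceSelect()]
#' @export
setClass("FeatureSelectionReport",
  representation(participants = "list", scores = "numeric",
                 regularization = "numeric", selected = "character",
                 grid = "numeric"))

setValidity("FeatureSelectionReport", function(object) {
  msg <- character()
  if (length(object@participants) != length(object@scores))
    msg <- c(msg, "one score per evaluated subset required")
  if (any(object@scores < 0 | object@scores > 1))
    msg <- c(msg, "scores must lie in [0, 1]")
  if (!any(vapply(object@participants,
                  function(p) setequal(p, object@selected), logical(1))))
    msg <- c(msg, "selected subset must be among the participants")
  if (length(msg)) msg else TRUE
})

#' SubjectSplit: a subject-level train/test partition
#'
#' @slot trainIds,testIds disjoint subject identifier sets covering all
#'   subjects.
#' @slot foldIndex which fold of the experiment this split belongs to.
#'
#' @seealso [splitBySubject()]
#' @export
setClass("SubjectSplit",
  representation(trainIds = "character", testIds = "character",
                 foldIndex = "integer"))

setValidity("SubjectSplit", function(object) {
  if (length(intersect(object@trainIds, object@testIds)))
    return("train and test subjects must be disjoint")
  if (!length(object@trainIds) || !length(object@testIds))
    return("both train and test sets must be non-empty")
  TRUE
})

#' TrainedEstimator: a frozen linear maximum-margin voxel classifier
#'
#' Stores everything needed to reproduce a prediction: the ordered feature
#' names, the per-feature standardization parameters fitted on the training
#' rows, and the weights and bias of the linear decision function. A voxel
#' is classified as ventricle when
#' \code{sum(weights * (x - center) / scale) + bias > 0}.
#'
#' @slot featureNames ordered feature names.
#' @slot center,scale per-feature standardization mean and sd.
#' @slot weights linear decision weights, one per feature.
#' @slot bias scalar intercept of the decision function.
#' @slot metadata list with training provenance (subjects, seed, grid,
#'   chosen regularization, fold scores).
#'
#' @seealso [trainEstimator()], [predictMask()], [writeEstimator()]
#' @export
setClass("TrainedEstimator",
  representation(featureNames = "character", center = "numeric",
                 scale = "numeric", weights = "numeric", bias = "numeric",
                 metadata = "list"))

setValidity("TrainedEstimator", function(object) {
  n <- length(object@featureNames)
  if (length(object@weights) != n || length(object@center) != n ||
      length(object@scale) != n)
    return("weights, center and scale must match featureNames in length")
  if (any(object@scale <= 0))
    return("all standardization scales must be > 0")
  if (length(object@bias) != 1L)
    return("bias must be a scalar")
  TRUE
})

#' PhantomSpec: recipe for a synthetic T1-like brain phantom
#'
#' Describes a head made of concentric ellipsoids (white-matter core,
#' grey-matter shell, background exterior) with a mirrored pair of
#' ellipsoidal ventricle-like CSF structures inside the core, an optional
#' extra CSF-intensity cyst touching one ventricle, T1-ordered class mean
#' intensities, additive Gaussian noise clamped at zero (magnitude-image
#' convention), a global contrast multiplier and an isocenter offset.
#'
#' @slot dim integer grid dimensions.
#' @slot spacing voxel spacing in mm.
#' @slot classMeans named numeric c(bg, csf, gm, wm); must satisfy
#'   bg < csf < gm < wm (CSF dark, as in T1 contrast).
#' @slot noiseSd additive Gaussian noise standard deviation (>= 0).
#' @slot headAxes,wmAxes semi-axes (mm) of the grey-matter outer and
#'   white-matter core ellipsoids, both centred at the grid centre.
#' @slot ventricles list of ellipsoids, each list(center = mm offsets from
#'   the grid centre, semi = semi-axes mm).
#' @slot cyst optional ellipsoid (same structure) of CSF intensity placed
#'   outside the ventricle truth mask, or NULL.
#' @slot contrastScale global multiplier applied to class means.
#' @slot isocenterOffset mm displacement of the world origin from the grid
#'   centre.
#' @slot seed integer random seed making generation deterministic.
#'
#' @seealso [phantomSpec()], [generatePhantom()], [generateCohort()]
#' @export
setClass("PhantomSpec",
  representation(dim = "integer", spacing = "numeric", classMeans = "numeric",
                 noiseSd = "numeric", headAxes = "numeric", wmAxes = "numeric",
                 ventricles = "list", cyst = "listOrNULL",
                 contrastScale = "numeric", isocenterOffset = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@dim) != 3L || any(object@dim < 8L))
    msg <- c(msg, "dim must be three integers >= 8")
  if (!all(c("bg", "csf", "gm", "wm") %in% names(object@classMeans)))
    msg <- c(msg, "classMeans must name bg, csf, gm, wm")
  else {
    m <- object@classMeans
    if (!(m["bg"] < m["csf"] && m["csf"] < m["gm"] && m["gm"] < m["wm"]))
      msg <- c(msg, "class means must satisfy bg < csf < gm < wm")
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@contrastScale <= 0) msg <- c(msg, "contrastScale must be > 0")
  if (length(object@headAxes) != 3L || length(object@wmAxes) != 3L ||
      any(object@headAxes <= 0) || any(object@wmAxes <= 0))
    msg <- c(msg, "head and core semi-axes must be positive length-3")
  if (any(object@wmAxes >= object@headAxes))
    msg <- c(msg, "white-matter core must lie strictly inside the head")
  if (!length(object@ventricles))
    msg <- c(msg, "at least one ventricle ellipsoid is required")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeImage: %d x %d x %d voxels, spacing (%s) mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = ", ")))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("BinaryMask: %d x %d x %d voxels, %d positive (%.2f mm^3 each)\n",
              d[1], d[2], d[3], sum(object@data), prod(object@spacing)))
})

setMethod("show", "ParcellationBoundaries", function(object) {
  cat("ParcellationBoundaries:",
      paste(sprintf("p%d = %.4g", 1:4, object@cuts), collapse = ", "), "\n")
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d voxels x %d features (%s)\n",
              nrow(object@table), length(object@featureNames),
              paste(object@featureNames, collapse = ", ")))
  cat(sprintf("  subjects: %d; supervised: %s\n",
              length(unique(object@table$subject)),
              "label" %in% names(object@table)))
})

setMethod("show", "FeatureSelectionReport", function(object) {
  cat(sprintf("FeatureSelectionReport: %d subsets evaluated\n",
              length(object@participants)))
  cat(sprintf("  selected {%s}, score %.4f\n",
              paste(object@selected, collapse = ", "), max(object@scores)))
})

setMethod("show", "TrainedEstimator", function(object) {
  cat("TrainedEstimator (linear maximum-margin classifier)\n")
  cat("  features:", paste(object@featureNames, collapse = ", "), "\n")
  cat("  weights: ", paste(format(object@weights, digits = 4),
                           collapse = ", "),
      " bias:", format(object@bias, digits = 4), "\n")
})

setMethod("show", "SubjectSplit", function(object) {
  cat(sprintf("SubjectSplit fold %d: %d train / %d test subjects\n",
              object@foldIndex, length(object@trainIds),
              length(object@testIds)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s grid at (%s) mm, %d ventricle(s)%s, seed %d\n",
              paste(object@dim, collapse = "x"),
              paste(object@spacing, collapse = ", "),
              length(object@ventricles),
              if (is.null(object@cyst)) "" else " + cyst",
              object@seed))
})

## ---- accessors ----------------------------------------------------------

#' @rdname VolumeImage-class
#' @param object a VolumeImage or BinaryMask.
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))
#' @rdname VolumeImage-class
#' @export
setMethod("imageData", "VolumeImage", function(object) object@data)
#' @rdname BinaryMask-class
#' @param object a BinaryMask.
#' @export
setMethod("imageData", "BinaryMask", function(object) object@data)

#' @rdname VolumeImage-class
#' @export
setGeneric("imageAffine", function(object) standardGeneric("imageAffine"))
#' @rdname VolumeImage-class
#' @export
setMethod("imageAffine", "VolumeImage", function(object) object@affine)
#' @rdname BinaryMask-class
#' @export
setMethod("imageAffine", "BinaryMask", function(object) object@affine)

#' @rdname VolumeImage-class
#' @export
setGeneric("imageSpacing", function(object) standardGeneric("imageSpacing"))
#' @rdname VolumeImage-class
#' @export
setMethod("imageSpacing", "VolumeImage", function(object) object@spacing)
#' @rdname BinaryMask-class
#' @export
setMethod("imageSpacing", "BinaryMask", function(object) object@spacing)

#' @rdname FeatureTable-class
#' @param object a FeatureTable.
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))
#' @rdname FeatureTable-class
#' @export
setMethod("featureNames", "FeatureTable", function(object) object@featureNames)
#' @rdname TrainedEstimator-class
#' @export
setMethod("featureNames", "TrainedEstimator",
          function(object) object@featureNames)

#' @rdname FeatureTable-class
#' @export
setGeneric("featureData", function(object) standardGeneric("featureData"))
#' @rdname FeatureTable-class
#' @export
setMethod("featureData", "FeatureTable", function(object) object@table)

#' @rdname ParcellationBoundaries-class
#' @param object a ParcellationBoundaries.
#' @export
setGeneric("boundaryCuts", function(object) standardGeneric("boundaryCuts"))
#' @rdname ParcellationBoundaries-class
#' @export
setMethod("boundaryCuts", "ParcellationBoundaries", function(object) object@cuts)

## internal constructors (validity-checked)
newVolume <- function(data, affine, spacing) {
  new("VolumeImage", data = data, affine = affine, spacing = as.numeric(spacing))
}
newMask <- function(data, affine, spacing) {
  storage.mode(data) <- "logical"
  new("BinaryMask", data = data, affine = affine, spacing = as.numeric(spacing))
}
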