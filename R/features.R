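## Per-voxel features.
##
## Intensity alone cannot separate ventricular CSF from other dark tissue,
## so each voxel is described by four complementary quantities: its
## histogram intensity class (hci), its distance to the scanner isocenter
## (nd), the index of the coarse grid block it falls in (card) and a
## 26-direction relative-contrast count acting as a boundary detector
## (neig). A candidate pool (raw intensity, Laplacian, Laplacian of
## Gaussian) is retained for feature-selection experiments.

#' Normalized distance to the scanner isocenter
#'
#' The scanner central voxel (SCV) is the pre-image of the world origin
#' under the image affine; it may be fractional and may fall outside the
#' grid for restricted fields of view. Each voxel's feature value is its
#' Euclidean distance in index space to the SCV, multiplied by the voxel
#' size (the product of the spacing components). On the 1 mm isotropic
#' working grid the multiplier is 1 and the value is the distance in mm.
#'
#' @param vol a [VolumeImage-class].
#' @return numeric 3D array of non-negative distances.
#' @export
normalizedDistance <- function(vol) {
  d <- dim(vol@data)
  scv <- solve(vol@affine, c(0, 0, 0, 1))[1:3]
  vsize <- prod(vol@spacing)
  dx2 <- (seq_len(d[1]) - 1 - scv[1])^2
  dy2 <- (seq_len(d[2]) - 1 - scv[2])^2
  dz2 <- (seq_len(d[3]) - 1 - scv[3])^2
  dist2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  sqrt(dist2) * vsize
}

#' Cardinality: coarse block-position index
#'
#' The field of view is divided into axis-aligned blocks of
#' `dividers` voxels per edge and each block receives a consecutive
#' integer, incrementing along x, then y, then z. Voxels in the same block
#' share a value, giving the classifier a coarse absolute position that
#' disambiguates radially equidistant voxels.
#'
#' @param vol a [VolumeImage-class].
#' @param dividers integer length-3 block edge lengths in voxels (default
#'   16 per axis). Dividers exceeding an axis are clamped to its length.
#' @return numeric 3D array of positive integer block indices.
#' @export
cardinalityFeature <- function(vol, dividers = c(16L, 16L, 16L)) {
  d <- dim(vol@data)
  dividers <- as.integer(round(dividers))
  if (length(dividers) != 3L || any(dividers < 1L))
    stopInvalidArgument("dividers must be three integers >= 1")
  dividers <- pmin(dividers, d)
  nBlocks <- ceiling(d / dividers)
  bx <- (seq_len(d[1]) - 1L) %/% dividers[1]
  by <- (seq_len(d[2]) - 1L) %/% dividers[2]
  bz <- (seq_len(d[3]) - 1L) %/% dividers[3]
  idx <- outer(outer(bx, by * nBlocks[1], "+"),
               bz * nBlocks[1] * nBlocks[2], "+") + 1
  idx * 1.0
}

## the 26 neighbourhood offsets (components in -1/0/1, excluding origin)
neighborOffsets <- function() {
  g <- as.matrix(expand.grid(a = -1:1, b = -1:1, c = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

#' Neighboring: 26-direction relative-contrast count
#'
#' For each of the 26 directions from a voxel V, let V_N be the immediate
#' neighbour and V_NN the next voxel in the same direction. The direction
#' counts 1 when `|I(V) - I(V_N)| > ratio * |I(V_N) - I(V_NN)|` (strict
#' inequality), so the feature is an integer between 0 and 26. Directions
#' whose V_N or V_NN fall outside the field of view contribute 0, so
#' border voxels attain smaller maxima.
#'
#' @param vol a [VolumeImage-class] with at least 3 voxels per axis.
#' @param ratio contrast threshold multiplier (default 0.2).
#' @return numeric 3D array of counts in [0, 26].
#' @export
neighboringFeature <- function(vol, ratio = 0.2) {
  d <- dim(vol@data)
  if (any(d < 3L))
    stopInvalidArgument("volume must have at least 3 voxels per axis")
  if (!is.finite(ratio) || ratio <= 0)
    stopInvalidArgument("ratio must be > 0")
  A <- vol@data
  counts <- array(0, dim = d)
  rangeFor <- function(n, off, steps) {
    ## centre indices (1-based) for which centre + steps*off stays in 1..n
    lo <- 1L + max(0L, -steps * off)
    hi <- n - max(0L, steps * off)
    lo:hi
  }
  offsets <- neighborOffsets()
  for (k in seq_len(nrow(offsets))) {
    o <- offsets[k, ]
    cx <- rangeFor(d[1], o[1], 2L); cy <- rangeFor(d[2], o[2], 2L)
    cz <- rangeFor(d[3], o[3], 2L)
    V   <- A[cx, cy, cz, drop = FALSE]
    VN  <- A[cx + o[1], cy + o[2], cz + o[3], drop = FALSE]
    VNN <- A[cx + 2L * o[1], cy + 2L * o[2], cz + 2L * o[3], drop = FALSE]
    hit <- abs(V - VN) > ratio * abs(VN - VNN)
    counts[cx, cy, cz] <- counts[cx, cy, cz] + hit
  }
  counts
}

## shift an array by one voxel along axis, replicating the edge
shiftReplicate <- function(A, axis, by) {
  d <- dim(A)
  idx <- lapply(d, seq_len)
  s <- pmin(pmax(seq_len(d[axis]) - by, 1L), d[axis])
  idx[[axis]] <- s
  do.call(`[`, c(list(A), idx))
}

## 6-connected discrete Laplacian with edge replication
discreteLaplacian <- function(A) {
  out <- -6 * A
  for (axis in 1:3)
    for (by in c(-1L, 1L))
      out <- out + shiftReplicate(A, axis, by)
  out
}

## separable 3D Gaussian smoothing (sigma in voxels), edge-renormalized
gaussianSmooth3d <- function(A, sigma) {
  d <- dim(A)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  smoothAxis <- function(A, axis) {
    n <- dim(A)[axis]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - r):min(n, i + r)
      w <- k[j - i + r + 1L]
      K[i, j] <- w / sum(w)
    }
    perm <- c(axis, setdiff(1:3, axis))
    M <- aperm(A, perm)
    dm <- dim(M)
    M <- K %*% matrix(M, nrow = dm[1])
    aperm(array(M, dm), order(perm))
  }
  for (axis in 1:3) A <- smoothAxis(A, axis)
  A
}

#' Candidate feature pool
#'
#' The wider pool explored during feature selection: the raw intensity,
#' the 6-connected discrete Laplacian (a boundary detector) and the
#' Laplacian of Gaussian at sigma = 1, 2, 3 voxels.
#'
#' @param vol a [VolumeImage-class].
#' @return named list of 3D arrays: `intensity`, `laplacian`, `log_s1`,
#'   `log_s2`, `log_s3`.
#' @export
candidatePool <- function(vol) {
  A <- vol@data
  list(intensity = A,
       laplacian = discreteLaplacian(A),
       log_s1 = discreteLaplacian(gaussianSmooth3d(A, 1)),
       log_s2 = discreteLaplacian(gaussianSmooth3d(A, 2)),
       log_s3 = discreteLaplacian(gaussianSmooth3d(A, 3)))
}

#' Compute named feature volumes for one subject
#'
#' @param vol a [VolumeImage-class].
#' @param features character vector of feature names among `hci`, `nd`,
#'   `card`, `neig`, `intensity`, `laplacian`, `log_s1`, `log_s2`,
#'   `log_s3`.
#' @param cardinalityDividers block edge lengths for [cardinalityFeature()].
#' @param neighborRatio contrast ratio for [neighboringFeature()].
#' @param nBins histogram bins for [hciFeature()].
#' @return named list of 3D feature arrays, in the order of `features`.
#' @export
extractFeatures <- function(vol, features = c("hci", "nd", "card", "neig"),
                            cardinalityDividers = c(16L, 16L, 16L),
                            neighborRatio = 0.2, nBins = 256L) {
  pool <- NULL
  getPool <- function() {
    if (is.null(pool)) pool <<- candidatePool(vol)
    pool
  }
  out <- lapply(features, function(f) {
    switch(f,
      hci = hciFeature(vol, nBins = nBins),
      nd = normalizedDistance(vol),
      card = cardinalityFeature(vol, cardinalityDividers),
      neig = neighboringFeature(vol, neighborRatio),
      intensity = , laplacian = , log_s1 = , log_s2 = , log_s3 =
        getPool()[[f]],
      stopMissingFeature(paste("unknown feature:", f)))
  })
  names(out) <- features
  out
}

#' Assemble the supervised per-voxel feature table
#'
#' One row per voxel per volume, with feature columns in the requested
#' order, the supervising label taken from the paired mask (0 everywhere
#' when no mask is supplied), and the subject identifier. Voxel grid
#' coordinates are retained so predictions can be reassembled into masks.
#'
#' @param vols named list of [VolumeImage-class] objects (names are the
#'   subject identifiers), all on a common isotropic grid spacing.
#' @param masks optional named list of [BinaryMask-class] objects aligned
#'   to the volumes; `NULL` entries are allowed.
#' @param features ordered feature names (see [extractFeatures()]).
#' @param ... passed to [extractFeatures()].
#' @return a [FeatureTable-class].
#' @export
buildFeatureTable <- function(vols, masks = NULL,
                              features = c("hci", "nd", "card", "neig"),
                              ...) {
  if (!length(vols)) stopInvalidArgument("at least one volume is required")
  ids <- names(vols)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_along(vols))
  pieces <- vector("list", length(vols))
  for (i in seq_along(vols)) {
    vol <- vols[[i]]
    d <- dim(vol@data)
    mask <- if (!is.null(masks)) masks[[i]] else NULL
    if (!is.null(mask) && !identical(dim(mask@data), d))
      stopAlignmentError(sprintf(
        "mask grid (%s) does not match volume grid (%s) for subject %s",
        paste(dim(mask@data), collapse = "x"), paste(d, collapse = "x"),
        ids[i]))
    fv <- extractFeatures(vol, features, ...)
    idx <- voxelIndexGrid(d)
    df <- data.frame(subject = ids[i], x = idx[, 1], y = idx[, 2],
                     z = idx[, 3])
    for (f in features) df[[f]] <- as.numeric(fv[[f]])
    df$label <- if (is.null(mask)) 0 else as.numeric(mask@data)
    pieces[[i]] <- df
  }
  tab <- do.call(rbind, pieces)
  rownames(tab) <- NULL
  new("FeatureTable", table = tab, featureNames = features)
}

#' Write a feature table to CSV
#'
#' Column order: features, label (when present), subject.
#'
#' @param table a [FeatureTable-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFeatureTable <- function(table, path) {
  cols <- c(table@featureNames,
            intersect("label", names(table@table)), "subject")
  utils::write.csv(table@table[, cols], path, row.names = FALSE)
  invisible(path)
}
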