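## The statistical estimator: per-feature standardization, subject-grouped
## splitting, regularization tuning and linear maximum-margin training,
## plus voxel-wise prediction reassembled into a mask.

#' Subject-grouped train/test splits
#'
#' Returns `folds` independent splits; in each, `round(fraction * n)`
#' subjects are drawn (seeded, re-randomized per fold) into the training
#' set and the rest form the test set. Splitting at the subject level makes
#' voxel leakage between train and test impossible by construction.
#'
#' @param subjectIds subject identifiers (>= 2 unique values).
#' @param fraction training fraction in (0, 1); default 0.75.
#' @param folds number of splits; default 6.
#' @param seed integer seed.
#' @return list of [SubjectSplit-class] objects.
#' @examples
#' sp <- splitBySubject(sprintf("S%02d", 1:44))
#' lengths(list(sp[[1]]@trainIds, sp[[1]]@testIds))  # 33 / 11
#' @export
splitBySubject <- function(subjectIds, fraction = 0.75, folds = 6L,
                           seed = 1L) {
  ids <- unique(as.character(subjectIds))
  n <- length(ids)
  if (n < 2L) stopInvalidSplit("at least 2 subjects are required")
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
    stopInvalidArgument("fraction must lie strictly between 0 and 1")
  nTrain <- round(fraction * n)
  if (nTrain < 1L || nTrain >= n)
    stopInvalidSplit(sprintf(
      "fraction %.2f of %d subjects leaves an empty train or test set",
      fraction, n))
  withSeed(seed, lapply(seq_len(folds), function(f) {
    tr <- sample(ids, nTrain)
    new("SubjectSplit", trainIds = sort(tr),
        testIds = sort(setdiff(ids, tr)), foldIndex = as.integer(f))
  }))
}

#' Standardize feature columns
#'
#' z-scores the feature columns of a table. When `params` is `NULL` the
#' mean and sd of every feature are fitted on the given rows; otherwise the
#' supplied parameters are applied (out-of-sample behaviour). Label and
#' subject columns are untouched.
#'
#' @param table a [FeatureTable-class].
#' @param params `NULL`, or a list with numeric vectors `center` and
#'   `scale` named by feature.
#' @return list with elements `table` (the scaled [FeatureTable-class])
#'   and `params`.
#' @export
standardizeFeatures <- function(table, params = NULL) {
  stopifnot(is(table, "FeatureTable"))
  feats <- table@featureNames
  X <- as.matrix(table@table[, feats, drop = FALSE])
  if (is.null(params)) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    if (any(scale == 0))
      stopDegenerateFeature(paste(
        "zero-variance feature(s):",
        paste(feats[scale == 0], collapse = ", ")))
    params <- list(center = center, scale = scale)
  }
  Xs <- scale(X, params$center[feats], params$scale[feats])
  tab <- table@table
  tab[feats] <- as.data.frame(Xs)
  list(table = new("FeatureTable", table = tab, featureNames = feats),
       params = params)
}

## seeded stratified row subsampling: keep all positives (up to a cap
## implied by maxRows), draw negRatio negatives per positive
subsampleRows <- function(y, negRatio, maxRows, seed) {
  pos <- which(y == 1)
  neg <- which(y == 0)
  withSeed(seed, {
    nNeg <- min(length(neg), ceiling(negRatio * length(pos)))
    keepNeg <- if (nNeg < length(neg)) sample(neg, nNeg) else neg
    keep <- c(pos, keepNeg)
    if (length(keep) > maxRows) {
      fracPos <- length(pos) / length(keep)
      nPos <- max(2L, round(maxRows * fracPos))
      nNeg2 <- maxRows - nPos
      keep <- c(if (nPos < length(pos)) sample(pos, nPos) else pos,
                sample(keepNeg, min(nNeg2, length(keepNeg))))
    }
    sort(keep)
  })
}

#' Train the voxel classifier
#'
#' Fits per-feature standardization on the training rows, selects the
#' regularization strength by subject-grouped cross-validation within the
#' training subjects, and fits the final linear maximum-margin classifier.
#' Cross-validated candidates are ranked by the voxel-level Jaccard
#' overlap of the positive class, not raw accuracy: with ventricle voxels
#' below 1% of a head, accuracy barely registers a one-voxel error shell
#' around the ventricle surface, while the overlap (and any volume
#' derived from the mask) is dominated by it. Fold models are fitted on
#' the subsampled rows but evaluated on every voxel of the held-out
#' subjects, so the selection sees the imbalance the deployed classifier
#' will face.
#' Ventricle voxels are a small fraction of a head volume, so the negative
#' class is subsampled at `negRatio` negatives per positive (seeded) and
#' inverse-frequency class weights are applied; both defaults can be
#' changed.
#'
#' @param table a supervised [FeatureTable-class].
#' @param split optional [SubjectSplit-class]; when given, only its
#'   training subjects are used (the published estimator is trained on all
#'   subjects after fold-wise evaluation, so the default `NULL` uses every
#'   subject).
#' @param grid regularization strengths to tune over.
#' @param seed integer seed (fold assignment and subsampling).
#' @param classWeights apply inverse-frequency class weights (default
#'   TRUE).
#' @param negRatio negatives kept per positive row (default 3); `Inf`
#'   keeps all.
#' @param maxRows cap on rows entering the optimizer (default 20000).
#' @param tuneFolds subject-grouped folds for the regularization search
#'   (default 3).
#' @return a [TrainedEstimator-class].
#' @export
trainEstimator <- function(table, split = NULL,
                           grid = defaultRegularizationGrid(), seed = 1L,
                           classWeights = TRUE, negRatio = 3,
                           maxRows = 20000L, tuneFolds = 3L) {
  stopifnot(is(table, "FeatureTable"))
  if (!"label" %in% names(table@table))
    stopDegenerateLabels("a supervised table with labels is required")
  tab <- table@table
  if (!is.null(split)) {
    stopifnot(is(split, "SubjectSplit"))
    tab <- tab[tab$subject %in% split@trainIds, , drop = FALSE]
  }
  y <- tab$label
  if (length(unique(y)) < 2L)
    stopDegenerateLabels("training rows contain a single class")
  feats <- table@featureNames
  X <- as.matrix(tab[, feats, drop = FALSE])
  center <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stopDegenerateFeature(paste("zero-variance feature(s):",
                                paste(feats[sds == 0], collapse = ", ")))
  Xs <- scale(X, center, sds)

  keep <- subsampleRows(y, negRatio, maxRows, seed)
  yk <- y[keep]
  cw <- if (classWeights) {
    tabY <- table(factor(yk, levels = c(0, 1)))
    stats::setNames(sum(tabY) / (2 * as.numeric(tabY)), names(tabY))
  } else NULL

  ## regularization search by subject-grouped CV within the training set:
  ## fold models are fitted on subsampled rows, scored by positive-class
  ## Jaccard overlap over all rows of the held-out subjects
  bestCost <- grid[1]
  foldScores <- NULL
  subjects <- tab$subject
  if (length(grid) > 1L && length(unique(subjects)) >= tuneFolds) {
    foldOf <- assignFolds(subjects, tuneFolds, seed)
    rowFold <- foldOf[subjects]
    acc <- matrix(NA_real_, length(grid), tuneFolds)
    for (f in seq_len(tuneFolds)) {
      tr <- which(rowFold != f)
      te <- which(rowFold == f)
      if (length(unique(y[tr])) < 2L || !length(te)) next
      keepTr <- tr[subsampleRows(y[tr], negRatio, maxRows, seed + f)]
      Xtr <- Xs[keepTr, , drop = FALSE]
      ytr <- y[keepTr]
      Xte <- Xs[te, , drop = FALSE]
      yte <- y[te]
      for (ci in seq_along(grid)) {
        m <- fitLinearSVM(Xtr, ytr, grid[ci], cw)
        pred <- decisionValues(m, Xte) > 0
        uni <- sum(pred | yte == 1)
        acc[ci, f] <- if (uni == 0) 1 else sum(pred & yte == 1) / uni
      }
    }
    meanAcc <- rowMeans(acc, na.rm = TRUE)
    bestCost <- grid[which.max(meanAcc)]
    foldScores <- meanAcc[which.max(meanAcc)]
  }

  final <- fitLinearSVM(Xs[keep, , drop = FALSE], yk, bestCost, cw)
  new("TrainedEstimator",
      featureNames = feats,
      center = center, scale = sds,
      weights = stats::setNames(final$weights, feats), bias = final$bias,
      metadata = list(subjects = sort(unique(tab$subject)),
                      seed = as.integer(seed), grid = grid,
                      cost = bestCost, cvOverlap = foldScores,
                      nRows = length(keep),
                      classWeights = as.list(cw)))
}

#' Classify every voxel of a volume into a mask
#'
#' Applies the frozen standardization and linear decision function to the
#' supplied feature volumes; voxels with positive margin form the
#' predicted mask. No post-processing is applied by default; setting
#' `largestComponent = TRUE` keeps only the largest 6-connected component.
#'
#' @param estimator a [TrainedEstimator-class].
#' @param vol the [VolumeImage-class] the features were computed from
#'   (supplies grid and geometry).
#' @param featureVolumes named list of 3D feature arrays covering the
#'   estimator's features; computed from `vol` via [extractFeatures()]
#'   when omitted.
#' @param largestComponent restrict the mask to its largest connected
#'   component (default FALSE).
#' @param ... passed to [extractFeatures()] when features are computed
#'   here.
#' @return a [BinaryMask-class].
#' @export
predictMask <- function(estimator, vol, featureVolumes = NULL,
                        largestComponent = FALSE, ...) {
  stopifnot(is(estimator, "TrainedEstimator"), is(vol, "VolumeImage"))
  feats <- estimator@featureNames
  if (is.null(featureVolumes))
    featureVolumes <- extractFeatures(vol, feats, ...)
  missing <- setdiff(feats, names(featureVolumes))
  if (length(missing))
    stopMissingFeature(paste("missing feature volume(s):",
                             paste(missing, collapse = ", ")))
  d <- dim(vol@data)
  for (f in feats)
    if (!identical(dim(featureVolumes[[f]]), d))
      stopAlignmentError(paste("feature volume grid mismatch for", f))
  X <- vapply(feats, function(f) as.numeric(featureVolumes[[f]]),
              numeric(prod(d)))
  Xs <- scale(X, estimator@center, estimator@scale)
  dec <- drop(Xs %*% estimator@weights + estimator@bias)
  maskArr <- array(dec > 0, dim = d)
  if (largestComponent && any(maskArr))
    maskArr <- largestConnectedComponent(maskArr)
  newMask(maskArr, vol@affine, vol@spacing)
}

## largest 6-connected component via flood fill
largestConnectedComponent <- function(maskArr) {
  d <- dim(maskArr)
  labels <- array(0L, dim = d)
  cur <- 0L
  idxAll <- which(maskArr)
  sizes <- integer()
  for (start in idxAll) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    sz <- 0L
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      sz <- sz + 1L
      k <- v - 1L
      x <- k %% d[1]; y <- (k %/% d[1]) %% d[2]; z <- k %/% (d[1] * d[2])
      for (off in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                       c(0, 0, -1), c(0, 0, 1))) {
        nx <- x + off[1]; ny <- y + off[2]; nz <- z + off[3]
        if (nx < 0 || ny < 0 || nz < 0 || nx >= d[1] || ny >= d[2] ||
            nz >= d[3]) next
        ni <- 1L + nx + d[1] * (ny + d[2] * nz)
        if (maskArr[ni] && labels[ni] == 0L) {
          labels[ni] <- cur
          queue <- c(queue, ni)
        }
      }
    }
    sizes[cur] <- sz
  }
  labels == which.max(sizes)
}

#' Persist an estimator as JSON
#'
#' The estimator is stored as a versioned, human-readable JSON document
#' (feature names, standardization parameters, weights, bias, metadata) so
#' that models are portable and diffable; no opaque binary serialization
#' is used.
#'
#' @param estimator a [TrainedEstimator-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEstimator <- function(estimator, path) {
  doc <- list(
    format = "ventvol-estimator",
    version = 1L,
    featureNames = estimator@featureNames,
    center = as.list(stats::setNames(estimator@center,
                                     estimator@featureNames)),
    scale = as.list(stats::setNames(estimator@scale,
                                    estimator@featureNames)),
    weights = as.list(stats::setNames(estimator@weights,
                                      estimator@featureNames)),
    bias = estimator@bias,
    metadata = estimator@metadata)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeEstimator
#' @export
readEstimator <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "ventvol-estimator"))
    stopInvalidArgument("not a ventvol estimator document")
  feats <- doc$featureNames
  new("TrainedEstimator",
      featureNames = feats,
      center = unlist(doc$center)[feats],
      scale = unlist(doc$scale)[feats],
      weights = unlist(doc$weights)[feats],
      bias = doc$bias,
      metadata = as.list(doc$metadata))
}
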