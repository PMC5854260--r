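## End-to-end orchestration: simulate/load -> resample -> features ->
## folds -> train -> segment -> evaluate.

asVolumeList <- function(volumes) {
  if (is.character(volumes)) {
    files <- if (length(volumes) == 1L && dir.exists(volumes))
      list.files(volumes, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
    else volumes
    out <- lapply(files, loadVolume)
    names(out) <- sub("\\.nii(\\.gz)?$", "", basename(files))
    out
  } else volumes
}

#' Run the training pipeline
#'
#' Resamples every volume (and mask) to the isotropic working grid,
#' extracts the per-voxel features, evaluates subject-grouped
#' train/test folds, and finally trains the published estimator on all
#' subjects. Fully reproducible from the inputs and seeds.
#'
#' @param volumes named list of [VolumeImage-class] (or a directory / file
#'   paths of NIfTI volumes).
#' @param masks list of [BinaryMask-class] matching `volumes` (or paths).
#' @param features ordered feature names (default the four selected
#'   features `hci`, `nd`, `card`, `neig`).
#' @param target isotropic working resolution in mm (default 1).
#' @param fraction training fraction per fold (default 0.75).
#' @param folds number of evaluation folds (default 6).
#' @param seed integer seed.
#' @param verbose print per-stage progress (default FALSE).
#' @param ... passed to [trainEstimator()] (e.g. `negRatio`, `maxRows`).
#' @return list with `estimator` (a [TrainedEstimator-class]), `foldReport`
#'   (data.frame with one row per fold: train/test subject counts and
#'   voxel-level test accuracy) and `table` (the assembled
#'   [FeatureTable-class]).
#' @export
runTrainingPipeline <- function(volumes, masks,
                                features = c("hci", "nd", "card", "neig"),
                                target = 1, fraction = 0.75, folds = 6L,
                                seed = 1L, verbose = FALSE, ...) {
  volumes <- asVolumeList(volumes)
  if (is.character(masks)) {
    files <- if (length(masks) == 1L && dir.exists(masks))
      list.files(masks, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
    else masks
    masks <- lapply(files, loadMask)
  }
  if (length(volumes) < 2L)
    stopInvalidSplit("at least 2 labelled subjects are required")
  say <- function(...) if (verbose) message(sprintf(...))
  say("resampling %d volumes to %g mm", length(volumes), target)
  volumes <- lapply(volumes, resampleIsotropic, target = target)
  masks <- lapply(masks, resampleMask, target = target)
  say("extracting features: %s", paste(features, collapse = ", "))
  tab <- buildFeatureTable(volumes, masks, features)
  say("feature table: %d rows", nrow(tab@table))
  splits <- splitBySubject(names(volumes), fraction, folds, seed)
  foldReport <- do.call(rbind, lapply(splits, function(sp) {
    est <- trainEstimator(tab, split = sp, seed = seed, ...)
    te <- tab@table[tab@table$subject %in% sp@testIds, , drop = FALSE]
    X <- scale(as.matrix(te[, features, drop = FALSE]),
               est@center, est@scale)
    acc <- mean((drop(X %*% est@weights + est@bias) > 0) == (te$label == 1))
    say("fold %d: %d train / %d test subjects, test accuracy %.4f",
        sp@foldIndex, length(sp@trainIds), length(sp@testIds), acc)
    data.frame(fold = sp@foldIndex, nTrain = length(sp@trainIds),
               nTest = length(sp@testIds), testAccuracy = acc)
  }))
  say("training final estimator on all %d subjects", length(volumes))
  estimator <- trainEstimator(tab, split = NULL, seed = seed, ...)
  list(estimator = estimator, foldReport = foldReport, table = tab)
}

#' Run the segmentation pipeline
#'
#' Segments each volume with a trained estimator and, when truth masks are
#' supplied, appends a comparison row (volumes, signed difference, Jaccard
#' index). A failing subject is reported and skipped; the remaining
#' subjects are still processed.
#'
#' @param volumes named list of [VolumeImage-class] (or directory / paths).
#' @param estimator a [TrainedEstimator-class].
#' @param truthMasks optional list of [BinaryMask-class] (or paths),
#'   aligned per subject; entries may be `NULL`.
#' @param target isotropic working resolution in mm (default 1).
#' @param outputDir optional directory where predicted masks are written
#'   as NIfTI.
#' @param ... passed to [extractFeatures()].
#' @return data.frame with one row per subject: subject id, automatic
#'   volume (mm^3) and - when truth is available - manual volume, signed
#'   difference and Jaccard index (NA otherwise).
#' @export
runSegmentationPipeline <- function(volumes, estimator, truthMasks = NULL,
                                    target = 1, outputDir = NULL, ...) {
  ## keep paths lazy so one unreadable subject cannot halt the batch
  if (is.character(volumes)) {
    files <- if (length(volumes) == 1L && dir.exists(volumes))
      list.files(volumes, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
    else volumes
    ids <- sub("\\.nii(\\.gz)?$", "", basename(files))
    getVolume <- function(i) loadVolume(files[i])
    n <- length(files)
  } else {
    ids <- names(volumes)
    if (is.null(ids)) ids <- sprintf("S%02d", seq_along(volumes))
    getVolume <- function(i) volumes[[i]]
    n <- length(volumes)
  }
  rows <- lapply(seq_len(n), function(i) {
    res <- tryCatch({
      vol <- resampleIsotropic(getVolume(i), target)
      pred <- predictMask(estimator, vol, ...)
      if (!is.null(outputDir)) {
        dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
        writeMask(pred, file.path(outputDir,
                                  paste0(ids[i], "_pred.nii.gz")))
      }
      truth <- if (!is.null(truthMasks)) truthMasks[[i]] else NULL
      if (!is.null(truth)) {
        truth <- resampleMask(truth, target)
        cmp <- compareSegmentations(truth, pred)
        data.frame(subject = ids[i], manualVolume = cmp$manualVolume,
                   autoVolume = cmp$autoVolume,
                   difference = cmp$difference, jaccard = cmp$jaccard)
      } else {
        data.frame(subject = ids[i], manualVolume = NA_real_,
                   autoVolume = maskVolume(pred), difference = NA_real_,
                   jaccard = NA_real_)
      }
    }, error = function(e) {
      warning(sprintf("subject %s failed during segmentation: %s",
                      ids[i], conditionMessage(e)), call. = FALSE)
      data.frame(subject = ids[i], manualVolume = NA_real_,
                 autoVolume = NA_real_, difference = NA_real_,
                 jaccard = NA_real_)
    })
    res
  })
  do.call(rbind, rows)
}
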