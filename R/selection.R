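## Exhaustive ("strong force") feature-subset selection.
##
## Every non-empty subset of the candidate features is scored by the mean
## cross-validated accuracy of a linear maximum-margin classifier tuned
## over a logarithmic regularization grid. Cross-validation folds are
## grouped by subject so voxels of one subject never appear on both sides
## of a fold, which is what controls over-fitting in a voxel-based design.

#' Exhaustive feature-subset search
#'
#' Enumerates all `2^k - 1` non-empty subsets of `candidates`. For each
#' subset, per-feature standardization is fitted inside each training fold,
#' a linear maximum-margin classifier is fitted at every regularization
#' strength of `grid`, and the subset's score is the best (over the grid)
#' mean accuracy across the subject-grouped folds. The selected subset is
#' the argmax score, with ties broken toward the smaller subset.
#'
#' @param table a supervised [FeatureTable-class] with at least 2 subjects
#'   and both classes present.
#' @param candidates feature names to search over (default: all features
#'   of the table).
#' @param folds number of subject-grouped cross-validation folds (default
#'   5).
#' @param seed integer seed controlling the fold assignment.
#' @param grid regularization strengths; default 50 points log-spaced from
#'   1e-4 to 1e3.
#' @return a [FeatureSelectionReport-class].
#' @examples
#' tab <- syntheticSelectionTable(nSubjects = 4, rowsPerSubject = 30)
#' rep <- strongForceSelect(tab, folds = 2, grid = c(0.1, 1))
#' rep@selected
#' @export
strongForceSelect <- function(table, candidates = featureNames(table),
                              folds = 5L, seed = 1L,
                              grid = defaultRegularizationGrid()) {
  stopifnot(is(table, "FeatureTable"))
  if (!length(candidates))
    stopInvalidArgument("at least one candidate feature is required")
  missing <- setdiff(candidates, names(table@table))
  if (length(missing))
    stopMissingFeature(paste("unknown candidate feature(s):",
                             paste(missing, collapse = ", ")))
  if (!"label" %in% names(table@table))
    stopDegenerateLabels("table has no label column")
  y <- table@table$label
  if (length(unique(y)) < 2L)
    stopDegenerateLabels("both classes must be present")
  subjects <- table@table$subject
  foldOf <- assignFolds(subjects, folds, seed)
  rowFold <- foldOf[subjects]

  Xall <- as.matrix(table@table[, candidates, drop = FALSE])
  nSub <- length(candidates)
  subsets <- lapply(seq_len(2^nSub - 1L), function(bits) {
    candidates[bitwAnd(bits, 2^(seq_len(nSub) - 1L)) > 0]
  })

  ## pre-split fold data once; per subset just select columns
  foldData <- lapply(seq_len(folds), function(f) {
    tr <- rowFold != f
    list(train = which(tr), test = which(!tr))
  })

  scoreSubset <- function(feats) {
    cols <- match(feats, candidates)
    accPerC <- matrix(NA_real_, length(grid), folds)
    for (f in seq_len(folds)) {
      tr <- foldData[[f]]$train; te <- foldData[[f]]$test
      mu <- colMeans(Xall[tr, cols, drop = FALSE])
      sd <- apply(Xall[tr, cols, drop = FALSE], 2, stats::sd)
      if (any(sd == 0))
        stopDegenerateFeature(paste(
          "zero-variance feature in training fold:",
          paste(feats[sd == 0], collapse = ", ")))
      Xtr <- scale(Xall[tr, cols, drop = FALSE], mu, sd)
      Xte <- scale(Xall[te, cols, drop = FALSE], mu, sd)
      ytr <- y[tr]; yte <- y[te]
      for (ci in seq_along(grid)) {
        m <- fitLinearSVM(Xtr, ytr, grid[ci])
        accPerC[ci, f] <- mean(predictLabels(m, Xte) == yte)
      }
    }
    meanAcc <- rowMeans(accPerC)
    best <- which.max(meanAcc)
    c(score = meanAcc[best], cost = grid[best])
  }

  res <- vapply(subsets, scoreSubset, numeric(2))
  scores <- res["score", ]
  sizes <- lengths(subsets)
  ord <- order(-scores, sizes)
  selected <- subsets[[ord[1]]]
  new("FeatureSelectionReport", participants = subsets, scores = scores,
      regularization = res["cost", ], selected = selected, grid = grid)
}

#' Serialize a selection report
#'
#' @param report a [FeatureSelectionReport-class].
#' @param path output path; `.csv` writes a subset/score table, `.json` a
#'   full structured document.
#' @return the path, invisibly.
#' @export
writeSelectionReport <- function(report, path) {
  df <- data.frame(
    subset = vapply(report@participants, paste, character(1),
                    collapse = "+"),
    score = report@scores,
    regularization = report@regularization)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(subsets = df, selected = report@selected,
           grid = report@grid),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Synthetic feature table for selection experiments
#'
#' Builds a small supervised table with two informative features (class
#' means separated by `separationSd` standard deviations) and two pure
#' noise features, balanced classes, grouped by subject. Used by the
#' selection demonstrations and tests.
#'
#' @param nSubjects number of subjects.
#' @param rowsPerSubject voxel rows per subject.
#' @param separationSd class separation of the informative features in sd
#'   units (default 4).
#' @param seed integer seed.
#' @param shuffleLabels permute labels within subjects (for permutation
#'   null experiments).
#' @return a [FeatureTable-class] with features f1, f2, noise1, noise2.
#' @export
syntheticSelectionTable <- function(nSubjects = 8L, rowsPerSubject = 30L,
                                    separationSd = 4, seed = 1L,
                                    shuffleLabels = FALSE) {
  withSeed(seed, {
    n <- nSubjects * rowsPerSubject
    label <- rep_len(c(0, 1), n)
    df <- data.frame(
      subject = rep(sprintf("S%02d", seq_len(nSubjects)),
                    each = rowsPerSubject),
      x = seq_len(n) - 1, y = 0, z = 0,
      f1 = stats::rnorm(n) + separationSd * label,
      f2 = stats::rnorm(n) - separationSd * label,
      noise1 = stats::rnorm(n),
      noise2 = stats::rnorm(n),
      label = label)
    if (shuffleLabels) {
      for (s in unique(df$subject)) {
        i <- which(df$subject == s)
        df$label[i] <- sample(df$label[i])
      }
    }
    new("FeatureTable", table = df,
        featureNames = c("f1", "f2", "noise1", "noise2"))
  })
}
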