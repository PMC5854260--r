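## Histogram-based intensity parcellation.
##
## MR contrast varies between acquisitions, so fixed intensity thresholds do
## not transfer across scans. Instead the intensity histogram of each volume
## is examined: the smoothed histogram envelope is stretched onto a standard
## axis, the second difference of the envelope is raised to the fifth power
## (amplifying strong slope changes while preserving their sign), and the
## four most prominent positive peaks of that signal are taken as the cut
## points separating background, CSF, grey matter and white matter. Each
## voxel then receives a class label R1-R4 from the position of its
## intensity among the cut points.

#' Smoothed histogram envelope of a volume
#'
#' Builds the raw intensity histogram over `nBins` equal-width bins and
#' smooths the counts with a Gaussian kernel. The kernel is renormalized at
#' the histogram edges so total mass is conserved. The intensity axis is
#' also mapped linearly onto [0, 255] (the stretch map); peak detection
#' operates on this standardized axis and detected positions are mapped
#' back through the inverse.
#'
#' @param vol a [VolumeImage-class] with non-constant intensities.
#' @param nBins number of histogram bins (>= 16; default 256).
#' @param smoothSigma Gaussian smoothing standard deviation in bins
#'   (default 4; wide enough that the shot noise of a desk-scale
#'   histogram stays below genuine tissue-mode curvature in the second
#'   difference).
#' @return a [HistogramEnvelope-class].
#' @export
computeEnvelope <- function(vol, nBins = 256L, smoothSigma = 4) {
  if (nBins < 16L)
    stopInvalidArgument("nBins must be at least 16")
  x <- as.numeric(vol@data)
  rng <- range(x)
  if (diff(rng) == 0)
    stopDegenerateHistogram("constant image: histogram has no structure")
  breaks <- seq(rng[1], rng[2], length.out = nBins + 1L)
  counts <- tabulate(
    pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), nBins),
    nbins = nBins)
  env <- gaussianSmooth1d(counts, smoothSigma)
  centers <- (breaks[-1L] + breaks[-(nBins + 1L)]) / 2
  scale <- 255 / diff(rng)
  out <- new("HistogramEnvelope", binCenters = centers, envelope = env,
             stretch = c(scale, -rng[1] * scale))
  attr(out@envelope, "smoothSigma") <- smoothSigma
  out
}

## Gaussian smoothing with per-position kernel renormalization, so the
## total mass of the signal is preserved at the boundaries.
gaussianSmooth1d <- function(x, sigma) {
  if (sigma <= 0) return(as.numeric(x))
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  n <- length(x)
  padded <- c(rep(0, r), x, rep(0, r))
  sm <- stats::filter(padded, k, sides = 2)[(r + 1L):(r + n)]
  ## renormalize by the in-range kernel mass at each position
  wt <- stats::filter(c(rep(0, r), rep(1, n), rep(0, r)), k,
                      sides = 2)[(r + 1L):(r + n)]
  as.numeric(sm / wt)
}

## Topographic prominence of peak positions in a signal: height above the
## higher of the two lowest points separating the peak from higher terrain.
peakProminence <- function(signal, peaks) {
  sigMin <- min(signal)
  vapply(peaks, function(p) {
    h <- signal[p]
    left <- signal[seq_len(p - 1L)]
    right <- if (p < length(signal)) signal[(p + 1L):length(signal)] else numeric()
    saddleLeft <- if (!length(left)) sigMin else {
      hi <- which(left > h)
      if (!length(hi)) min(left)
      else if (max(hi) >= length(left)) h      # adjacent higher: no drop
      else min(left[(max(hi) + 1L):length(left)])
    }
    saddleRight <- if (!length(right)) sigMin else {
      hi <- which(right > h)
      if (!length(hi)) min(right)
      else if (min(hi) <= 1L) h
      else min(right[seq_len(min(hi) - 1L)])
    }
    h - max(saddleLeft, saddleRight)
  }, numeric(1))
}

#' Detect the four parcellation cut points
#'
#' The second difference of the stretched envelope is raised to the fifth
#' power (a sign-preserving amplification of strong inflections). Positive
#' local maxima of that signal are candidate cut points. An adaptive
#' threshold starts at half the maximum positive value and is halved
#' recursively until at least four peaks exceed it (at most
#' `maxIterations` relaxations). Peaks within the smoothing radius of the
#' ends of the observed intensity range are excluded: curvature there
#' reflects the onset of the histogram support (for example the rise of
#' the air noise floor from zero), not a boundary between classes. Surviving peaks are ranked by
#' topographic prominence and picked greedily under a minimum mutual
#' separation of twice the envelope smoothing width (two inflections
#' closer than the smoothing scale are one slope change, not two); the
#' four winners, mapped back through the inverse stretch, are returned in
#' ascending intensity order.
#'
#' @param env a [HistogramEnvelope-class].
#' @param maxIterations maximum number of threshold relaxations (default
#'   20).
#' @return a [ParcellationBoundaries-class].
#' @export
detectBoundaries <- function(env, maxIterations = 20L) {
  stretched <- env@stretch[1] * env@binCenters + env@stretch[2]
  d2 <- diff(env@envelope, differences = 2L)
  p5 <- d2^5
  n <- length(p5)
  if (n < 3L)
    stopParcellationFailure("envelope too short for curvature analysis")
  isMax <- p5 > 0 &
    p5 >= c(-Inf, p5[-n]) & p5 > c(p5[-1L], -Inf)
  sig <- attr(env@envelope, "smoothSigma")
  minSep <- max(1L, ceiling(2 * (if (is.null(sig)) 4 else sig)))
  cand <- which(isMax)
  cand <- cand[cand > minSep & cand <= n - minSep]
  if (!length(cand))
    stopParcellationFailure("no positive curvature peaks in the envelope")
  ## the threshold starts at half the maximum and is halved per iteration;
  ## halving is applied on the curvature amplitude scale, i.e. by 2^5 on
  ## the fifth-power signal, so the relaxation keeps pace with the dynamic
  ## range the fifth power creates
  pickSeparated <- function(found) {
    prom <- peakProminence(p5, found)
    keep <- integer()
    for (p in found[order(prom, decreasing = TRUE)]) {
      if (length(keep) && min(abs(keep - p)) < minSep) next
      keep <- c(keep, p)
      if (length(keep) == 4L) break
    }
    keep
  }
  thr <- 0.5 * max(p5[cand])
  keep <- integer()
  for (i in seq_len(maxIterations)) {
    found <- cand[p5[cand] >= thr]
    if (length(found) >= 4L) {
      keep <- pickSeparated(found)
      if (length(keep) == 4L) break
    }
    thr <- thr / 2^5
  }
  if (length(keep) < 4L)
    stopParcellationFailure(sprintf(
      "fewer than 4 separated inflection peaks after %d threshold relaxations",
      maxIterations))
  ## d2 element i corresponds to envelope bin i + 1
  pos <- sort(stretched[keep + 1L])
  cuts <- (pos - env@stretch[2]) / env@stretch[1]
  new("ParcellationBoundaries", cuts = cuts)
}

#' Assign histogram class labels R1-R4 to every voxel
#'
#' Labels follow lower-inclusive, upper-exclusive intervals:
#' R1 when I < p1, R2 when p1 <= I < p2, R3 when p2 <= I < p3 and R4 when
#' p3 <= I (intensities at or above p4 are clamped into R4 so every voxel
#' is labelled).
#'
#' @param vol a [VolumeImage-class].
#' @param boundaries a [ParcellationBoundaries-class].
#' @return an integer 3D array with values 1-4.
#' @export
assignLabels <- function(vol, boundaries) {
  stopifnot(is(boundaries, "ParcellationBoundaries"))
  lab <- findInterval(vol@data, boundaries@cuts[1:3]) + 1L
  array(lab, dim = dim(vol@data))
}

#' Histogram-classified intensity feature
#'
#' Convenience wrapper running [computeEnvelope()], [detectBoundaries()]
#' and [assignLabels()] on one volume; the per-voxel class index (1-4) is
#' the feature value.
#'
#' @inheritParams computeEnvelope
#' @param ... passed to [computeEnvelope()].
#' @return numeric 3D array of class indices.
#' @export
hciFeature <- function(vol, ...) {
  env <- computeEnvelope(vol, ...)
  b <- detectBoundaries(env)
  assignLabels(vol, b) * 1.0
}

#' Export envelope diagnostics as CSV
#'
#' Writes bin centres, envelope, the fifth-power curvature signal and a
#' peak indicator for plotting.
#'
#' @param env a [HistogramEnvelope-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
exportEnvelopeDiagnostics <- function(env, path) {
  d2 <- diff(env@envelope, differences = 2L)
  p5 <- c(NA, d2^5, NA)
  peak <- rep(FALSE, length(env@envelope))
  ok <- tryCatch(detectBoundaries(env), error = function(e) NULL)
  if (!is.null(ok))
    peak[vapply(ok@cuts, function(ct)
      which.min(abs(env@binCenters - ct)), integer(1))] <- TRUE
  utils::write.csv(
    data.frame(binCenter = env@binCenters, envelope = env@envelope,
               curvaturePower5 = p5, boundary = peak),
    path, row.names = FALSE)
  invisible(path)
}
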