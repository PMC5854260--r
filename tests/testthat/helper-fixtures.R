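# In-code fixtures shared across test files.

makeVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  new("VolumeImage", data = data, affine = aff, spacing = spacing)
}

makeMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  storage.mode(data) <- "logical"
  new("BinaryMask", data = data, affine = aff, spacing = spacing)
}

# histogram envelope built directly from an analytic density (no sampling)
analyticEnvelope <- function(density, from, to, nBins = 256L,
                             smoothSigma = 4, total = 1e5) {
  centers <- seq(from, to, length.out = nBins)
  counts <- density(centers)
  counts <- counts / sum(counts) * total
  env <- ventvol:::gaussianSmooth1d(counts, smoothSigma)
  scale <- 255 / (to - from)
  out <- new("HistogramEnvelope", binCenters = centers, envelope = env,
             stretch = c(scale, -from * scale))
  attr(out@envelope, "smoothSigma") <- smoothSigma
  out
}

# brute-force 26-direction neighboring oracle (naive triple loop)
neighboringOracle <- function(A, ratio = 0.2) {
  d <- dim(A)
  out <- array(0, dim = d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    cnt <- 0
    for (k in seq_len(nrow(offs))) {
      o <- offs[k, ]
      n1 <- c(x, y, z) + o
      n2 <- c(x, y, z) + 2 * o
      if (any(n1 < 1) || any(n1 > d) || any(n2 < 1) || any(n2 > d)) next
      if (abs(A[x, y, z] - A[n1[1], n1[2], n1[3]]) >
          ratio * abs(A[n1[1], n1[2], n1[3]] - A[n2[1], n2[2], n2[3]]))
        cnt <- cnt + 1
    }
    out[x, y, z] <- cnt
  }
  out
}
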