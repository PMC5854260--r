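## Synthetic T1-like brain phantoms.
##
## A phantom is a head built from concentric ellipsoids - a bright
## white-matter core, an intermediate grey-matter shell and dark exterior
## background - containing a mirrored pair of dark (CSF-intensity)
## ellipsoidal ventricles, with optional per-subject variation in ventricle
## size (up to hydrocephalus-like enlargement), global contrast, noise
## level and isocenter placement. Noise follows the magnitude-image
## (Rician) model: each voxel is the modulus of the class mean plus
## complex Gaussian noise, so air has a smooth Rayleigh noise floor and
## tissue is effectively Gaussian at the exercised signal-to-noise ratios.
## Ground-truth ventricle masks are rasterized from the same ellipsoids,
## so segmentation accuracy can be measured exactly.

#' Construct a phantom specification
#'
#' Defaults describe a desk-scale head: a 48 x 54 x 46 grid at 1 mm, a
#' grey-matter shell with outer semi-axes (22, 25, 21) mm around a
#' white-matter core (15, 18, 14) mm, and two mirrored ventricles of
#' semi-axes (4, 3, 2.5) mm centred 3.5 mm left/right of the midline.
#' Class means (bg 0, csf 35, gm 65, wm 95) with noise sd 5 give a
#' low-contrast T1-like appearance (white-matter signal-to-noise about
#' 19, typical of fast 1.5 T acquisitions); air carries only the
#' Rayleigh noise floor of the magnitude reconstruction.
#'
#' @param dim integer grid dimensions.
#' @param spacing voxel spacing in mm.
#' @param classMeans named intensities c(bg, csf, gm, wm), bg lowest and
#'   CSF darker than grey matter as in T1 contrast.
#' @param noiseSd additive Gaussian noise sd.
#' @param headAxes,wmAxes semi-axes (mm) of the grey-matter outer surface
#'   and the white-matter core.
#' @param ventricleCenters list of mm offsets of ventricle centres from
#'   the grid centre.
#' @param ventricleAxes semi-axes (mm) shared by the ventricles.
#' @param ventricleScale multiplier applied to `ventricleAxes`
#'   (hydrocephalus-like enlargement when > 1).
#' @param cyst `NULL`, or `TRUE` to attach a CSF-intensity cyst touching
#'   the right ventricle tip (a known confounder for intensity-based
#'   segmentation), or a list(center=, semi=) ellipsoid in mm.
#' @param contrastScale global multiplier on class means.
#' @param isocenterOffset mm displacement of the world origin from the
#'   grid centre.
#' @param seed integer seed.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(dim = c(48L, 54L, 46L), spacing = c(1, 1, 1),
                        classMeans = c(bg = 0, csf = 35, gm = 65, wm = 95),
                        noiseSd = 5,
                        headAxes = c(22, 25, 21), wmAxes = c(15, 18, 14),
                        ventricleCenters = list(c(-3.5, 0, 0), c(3.5, 0, 0)),
                        ventricleAxes = c(4, 3, 2.5),
                        ventricleScale = 1,
                        cyst = NULL,
                        contrastScale = 1,
                        isocenterOffset = c(0, 0, 0), seed = 1L) {
  ventricles <- lapply(ventricleCenters, function(ctr)
    list(center = ctr, semi = ventricleAxes * ventricleScale))
  if (isTRUE(cyst)) {
    tip <- ventricleCenters[[length(ventricleCenters)]]
    semi <- ventricleAxes * ventricleScale
    cyst <- list(center = c(tip[1] + semi[1] + 2.2, tip[2], tip[3]),
                 semi = c(2.2, 2.2, 2.2))
  }
  new("PhantomSpec", dim = as.integer(dim), spacing = as.numeric(spacing),
      classMeans = classMeans, noiseSd = noiseSd,
      headAxes = as.numeric(headAxes), wmAxes = as.numeric(wmAxes),
      ventricles = ventricles, cyst = cyst,
      contrastScale = contrastScale,
      isocenterOffset = as.numeric(isocenterOffset),
      seed = as.integer(seed))
}

## logical array of voxels inside an ellipsoid; coords in mm relative to
## the grid centre, evaluated at voxel centres
rasterizeEllipsoid <- function(dim, spacing, center, semi) {
  ctr <- (dim - 1) / 2
  u2 <- lapply(1:3, function(ax) {
    ((seq_len(dim[ax]) - 1 - ctr[ax]) * spacing[ax] - center[ax])^2 /
      semi[ax]^2
  })
  outer(outer(u2[[1]], u2[[2]], "+"), u2[[3]], "+") <= 1
}

#' Generate one phantom
#'
#' Deterministic given the spec's seed. The truth mask is the union of the
#' ventricle ellipsoids rasterized at voxel centres; the cyst, when
#' present, shares the CSF intensity but is excluded from the truth. The
#' affine is diagonal in the spacing and places the world origin (the
#' isocenter) at the grid centre plus `isocenterOffset`.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements `volume` ([VolumeImage-class]), `truth`
#'   ([BinaryMask-class]) and `subjectId`.
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  d <- spec@dim
  sp <- spec@spacing
  head <- rasterizeEllipsoid(d, sp, c(0, 0, 0), spec@headAxes)
  core <- rasterizeEllipsoid(d, sp, c(0, 0, 0), spec@wmAxes)
  truth <- array(FALSE, dim = d)
  for (v in spec@ventricles) {
    vox <- rasterizeEllipsoid(d, sp, v$center, v$semi)
    if (any(vox & !core))
      stopInvalidSpec("ventricle ellipsoid extends outside the white-matter core")
    truth <- truth | vox
  }
  cystVox <- NULL
  if (!is.null(spec@cyst)) {
    cystVox <- rasterizeEllipsoid(d, sp, spec@cyst$center, spec@cyst$semi)
    if (any(cystVox & !head))
      stopInvalidSpec("cyst ellipsoid extends outside the head")
    cystVox <- cystVox & !truth
  }
  m <- spec@classMeans * spec@contrastScale
  img <- array(m["bg"], dim = d)
  img[head] <- m["gm"]
  img[core] <- m["wm"]
  img[truth] <- m["csf"]
  if (!is.null(cystVox)) img[cystVox] <- m["csf"]
  if (spec@noiseSd > 0) {
    ## magnitude-image noise: modulus of signal + complex Gaussian noise
    noise <- withSeed(spec@seed,
                      stats::rnorm(2 * prod(d), sd = spec@noiseSd))
    re <- img + array(noise[seq_len(prod(d))], dim = d)
    im <- array(noise[prod(d) + seq_len(prod(d))], dim = d)
    img <- sqrt(re^2 + im^2)
  }
  ctr <- (d - 1) / 2 + spec@isocenterOffset / sp
  affine <- diag(c(sp, 1))
  affine[1:3, 4] <- -sp * ctr
  list(volume = newVolume(img, affine, sp),
       truth = newMask(truth, affine, sp),
       subjectId = sprintf("P%06d", spec@seed))
}

#' Generate a cohort of phantoms
#'
#' Draws `n` phantoms with per-subject jitter of ventricle size (spanning
#' normal to hydrocephalus-like enlargement), global contrast, noise level
#' and isocenter placement; everything is deterministic given `seed`.
#'
#' @param n number of subjects.
#' @param base a [PhantomSpec-class] serving as the template.
#' @param jitter list of ranges: `ventricleScale` (default c(0.7, 1.5)),
#'   `contrastScale` (c(0.85, 1.15)), `noiseSd` (c(4, 6.5)) and
#'   `isocenterOffset` (c(-1.5, 1.5) mm per axis). Set a range to a single
#'   value to disable that axis of variation.
#' @param seed integer seed.
#' @param cystSubjects indices of subjects that receive the cyst
#'   confounder (default none).
#' @return list of phantoms as returned by [generatePhantom()], with
#'   distinct subject ids.
#' @export
generateCohort <- function(n, base = phantomSpec(),
                           jitter = list(), seed = 1L,
                           cystSubjects = integer()) {
  if (n < 1L) stopInvalidArgument("n must be >= 1")
  jd <- list(ventricleScale = c(0.7, 1.5), contrastScale = c(0.85, 1.15),
             noiseSd = c(4, 6.5), isocenterOffset = c(-1.5, 1.5))
  jd[names(jitter)] <- jitter
  draws <- withSeed(seed, {
    lapply(seq_len(n), function(i) {
      r <- function(rg) if (length(rg) == 1L || rg[1] == rg[2]) rg[1] else
        stats::runif(1, rg[1], rg[2])
      list(vs = r(jd$ventricleScale), cs = r(jd$contrastScale),
           ns = r(jd$noiseSd),
           off = vapply(1:3, function(k) r(jd$isocenterOffset), numeric(1)),
           seed = sample.int(.Machine$integer.max %/% 2L, 1))
    })
  })
  lapply(seq_len(n), function(i) {
    dr <- draws[[i]]
    spec <- phantomSpec(
      dim = base@dim, spacing = base@spacing, classMeans = base@classMeans,
      noiseSd = dr$ns, headAxes = base@headAxes, wmAxes = base@wmAxes,
      ventricleCenters = lapply(base@ventricles, `[[`, "center"),
      ventricleAxes = base@ventricles[[1]]$semi,
      ventricleScale = dr$vs,
      cyst = if (i %in% cystSubjects) TRUE else NULL,
      contrastScale = dr$cs, isocenterOffset = dr$off, seed = dr$seed)
    ph <- generatePhantom(spec)
    ph$subjectId <- sprintf("S%03d", i)
    ph$spec <- spec
    ph
  })
}

#' Write a cohort to disk with a manifest
#'
#' Writes `<id>_volume.nii.gz` and `<id>_mask.nii.gz` per subject plus a
#' `manifest.csv` (subject id, seed, truth volume in mm^3, key spec
#' fields).
#'
#' @param cohort list returned by [generateCohort()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(ph) {
    writeVolume(ph$volume, file.path(dir, paste0(ph$subjectId,
                                                 "_volume.nii.gz")))
    writeMask(ph$truth, file.path(dir, paste0(ph$subjectId,
                                              "_mask.nii.gz")))
    data.frame(subject = ph$subjectId,
               seed = if (!is.null(ph$spec)) ph$spec@seed else NA_integer_,
               truthVolume = maskVolume(ph$truth),
               noiseSd = if (!is.null(ph$spec)) ph$spec@noiseSd else NA,
               contrastScale = if (!is.null(ph$spec))
                 ph$spec@contrastScale else NA)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
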