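---
title: "Voxel-wise estimation of brain ventricular volume"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise estimation of brain ventricular volume}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventvol)
```

## The problem

The volume of the cerebral ventricles — the CSF-filled cavities of the
brain — is a clinically meaningful number: hydrocephalus management, shunt
follow-up and many neurological work-ups turn on whether it has changed.
Manual delineation slice by slice is accurate but slow, operator-dependent
and rarely done outside research. Registration- and atlas-based automatic
methods assume a full head in the field of view and a contrast pattern
close to their template, assumptions routinely violated by clinical scans,
which crop the field of view and vary acquisition parameters from visit to
visit.

`ventvol` treats segmentation as voxel-wise classification. Each voxel of
a T1-weighted volume is described by four cheap, deliberately
complementary features, and a linear maximum-margin classifier decides
whether the voxel belongs to the ventricles. The union of positive voxels
is the segmentation; its voxel count times the voxel volume is the
ventricular volume. Nothing requires an atlas, a registration, or a second
modality, so the method applies to restricted fields of view and variable
protocols.

## The four features

All features are computed on a 1 mm isotropic resampling of the input
(trilinear for intensities, nearest-neighbour for masks — the masks must
stay binary).

**Histogram-classified intensity (`hci`).** MR intensities are relative:
the same tissue lands at different numbers in different acquisitions, so
fixed thresholds do not transfer. Instead the volume's own histogram is
parcellated. The histogram envelope (Gaussian-smoothed counts) is mapped
linearly onto a standard [0, 255] axis, its second difference is raised to
the fifth power — a sign-preserving amplification that exaggerates strong
slope changes and suppresses weak ones — and positive peaks of that signal
mark abrupt inflections of the envelope. The four most prominent peaks,
mapped back to the intensity axis, become cut points $p_1 < p_2 < p_3 <
p_4$, and every voxel is labelled R1 ($I < p_1$) through R4 ($p_3 \le I$).
On a T1 head image the four intervals track background, CSF, grey matter
and white matter. The label index (1–4) is the feature.

**Normalized distance (`nd`).** Ventricles sit near the centre of the
head, which scanner operators centre at the magnet isocenter. The image
affine maps voxel indices to scanner world coordinates, so the pre-image
of the world origin — the scanner central voxel, possibly fractional,
possibly outside a cropped grid — is known without any registration. The
feature is the index-space Euclidean distance to that point multiplied by
the voxel volume; on the mandated 1 mm grid the multiplier is 1 and the
value is simply the distance in mm. The formula is implemented exactly as
stated even though the multiplier has volume units, because on the working
grid the ambiguity is inert.

**Cardinality (`card`).** Distance is radially ambiguous: a left-temporal
and a right-parietal voxel can be equidistant from the isocenter. Dividing
the field of view into axis-aligned blocks (16 voxels per edge by
default) and numbering the blocks consecutively along x, then y, then z
gives each voxel a coarse absolute position that breaks the tie. The
printed closed form for this index collapses algebraically (a divisor
cancels), so the package implements the standard row-major block index
the accompanying figure describes.

**Neighboring (`neig`).** For each of the 26 directions around a voxel
$V$, with $V_N$ the immediate neighbour and $V_{NN}$ the next voxel in
the same direction, the direction counts 1 when $|I(V) - I(V_N)| > 0.2\,
|I(V_N) - I(V_{NN})|$. The count (0–26; less at the FOV border, where
out-of-range directions contribute 0) acts as a local boundary detector.
The prose description and the printed inequality of the source disagree in
direction; the inequality is implemented as printed.

A wider candidate pool — raw intensity, a 6-connected discrete Laplacian,
and Laplacians of Gaussians at sigma 1, 2, 3 voxels — is retained for
feature-selection experiments.

## Peak detection: numerical choices

Three numerical decisions in `detectBoundaries()` deserve explanation,
because the underlying recipe ("find the four most prominent peaks, with
an adaptive threshold") underdetermines them.

* **Threshold schedule.** The adaptive threshold starts at half the
  maximum positive value of the fifth-power signal and is relaxed until
  at least four acceptable peaks survive (at most 20 relaxations). Each
  relaxation halves the threshold *on the curvature amplitude scale*,
  i.e. divides the fifth-power threshold by $2^5$. Halving on the
  fifth-power scale directly would cover only $2^{20}$ of dynamic range
  while the fifth power routinely spreads genuine peaks across ten orders
  of magnitude, so the search would never reach the weaker class
  boundaries.
* **Envelope smoothing (default sigma = 4 bins of 256).** The second
  difference of a histogram of $\sim 10^5$ samples carries shot noise
  comparable to genuine tissue-mode curvature when smoothed at 2 bins;
  at 4 bins the spurious curvature falls well below the weakest real
  flank while two modes 30 intensity units apart remain resolved. The
  value is a property of desk-scale histograms, not of any particular
  phantom.
* **Peak separation and support edges.** Two local maxima closer than
  twice the smoothing width are one slope change, not two, so the four
  winners are picked greedily by topographic prominence under that
  minimum separation. Peaks within the same radius of the ends of the
  observed intensity range are excluded: curvature there measures the
  onset of the histogram support (for instance the rise of the air noise
  floor from zero in a magnitude image), not a boundary between tissue
  classes.

One caveat is documented rather than hidden: the positive peaks of the
second derivative sit at the *flank inflections* of the histogram modes,
roughly $\mu \pm \sqrt{3}\sigma$ for a Gaussian mode. When modes overlap
(separation below about $3.5\sigma$, the typical low-contrast clinical
case) the two facing flanks merge into a single peak near the density
minimum, and the cut point lands where an optimal threshold would. When
modes are far apart the cut points stay near the flanks instead of the
empty valley between them. The voxel labels are almost unchanged either
way — the intervals still bracket each class — but the cut points
themselves should not be interpreted as density minima. Consequently the
class assignment is imperfect in a predictable way: each tissue mode
keeps roughly 90–95% of its own voxels, with the flank tails spilling
into the neighbouring interval. What the downstream classifier needs, and
what the tests assert, is that ventricular CSF concentrates in one
interval which grey and white matter essentially never enter.

## The estimator

Feature columns are z-scored with parameters fitted on training rows
only. Data are always split **by subject** — a 0.75:0.25 subject split,
re-randomized over 6 folds for evaluation — so voxels of one subject
never appear on both sides of a fold; with tens of thousands of highly
correlated voxels per subject, any voxel-level split would leak. The
classifier is a linear soft-margin SVM; its regularization strength is
tuned on a 50-point logarithmic grid from $10^{-4}$ to $10^{3}$ by
subject-grouped cross-validation inside the training set, and the final
model is refit on all training rows at the chosen strength. The fitted
support-vector expansion is collapsed to explicit weights and bias, so a
frozen estimator is just `sign(w' z + b)` and serializes to a small JSON
document.

Ventricle voxels are well under 1% of a head volume. Training therefore
keeps every positive row and a seeded sample of 3 negatives per positive
(capped at 20 000 rows in total), and applies inverse-frequency class
weights. These sizes keep the quadratic-programming solver fast at desk
scale without changing the decision boundary materially; both are
configurable. Prediction thresholds the margin at zero — no probability
calibration, no post-processing by default (an optional
largest-connected-component filter exists behind a flag, off by default).

The exhaustive feature search (`strongForceSelect()`) scores **every**
non-empty subset of the candidate features by tuned, subject-grouped
cross-validated accuracy and returns the argmax, ties broken toward the
smaller subset. With $k$ candidates that is $2^k - 1$ subsets; the search
is exhaustive by design, not greedy, and is only intended for the small
candidate pools the feature engineering produces.

## The phantom generator

No clinical cohort ships with the package, so validation uses synthetic
T1-like phantoms with exact ground truth. A phantom is a head of
concentric ellipsoids — a bright white-matter core (semi-axes 15, 18,
14 mm), an intermediate grey-matter shell (22, 25, 21 mm), dark exterior —
containing a mirrored pair of CSF-dark ellipsoidal ventricles (4, 3,
2.5 mm semi-axes, centres 3.5 mm off the midline) on a 48 x 54 x 46 grid
at 1 mm. Class mean intensities are 0/35/65/95 (bg/CSF/GM/WM) in
arbitrary units with noise sd 5 — a white-matter SNR of about 19, the
low-contrast end of fast 1.5 T clinical imaging, which is exactly the
regime that defeats fixed thresholds and motivates histogram
parcellation.

Noise follows the magnitude-image model: each voxel is the modulus of the
class mean plus complex Gaussian noise. For tissue this is
indistinguishable from additive Gaussian noise at the SNRs exercised; for
air it produces the smooth Rayleigh noise floor every magnitude
reconstruction shows. A clamped additive-Gaussian model was rejected
because it concentrates half the background mass in a spike at exactly
zero — a histogram artifact no scanner produces and one that derails any
histogram-based method.

Cohorts jitter four axes per subject, emulating protocol variability:
ventricle scale U(0.7, 1.5) (volumes span roughly an order of magnitude,
up to hydrocephalus-like enlargement), global contrast U(0.85, 1.15),
noise sd U(4, 6.5) and isocenter offset U(-1.5, 1.5) mm per axis. An
optional confounder attaches a CSF-intensity cyst touching (never
overlapping) a ventricle tip — an arachnoid-cyst analogue that
intensity-plus-position features cannot distinguish from ventricle, which
reproduces the known failure mode of this class of methods: the affected
subject is over-segmented and its overlap score drops below the cohort
mean.

What the phantoms do **not** model: partial-volume mixing at tissue
interfaces, bias fields, k-space artifacts, anatomical shape realism, and
pathology other than ventricle enlargement and the cyst. Passing the
phantom suite therefore demonstrates that the pipeline recovers known
geometry under contrast/noise/position variability — not clinical-grade
accuracy on real scans.

## Scale of the shipped experiments

The test suite runs the full protocol at desk scale: a 40-phantom cohort
(30 training, 10 held-out test — mirroring the published 44-train,
10-test design at reduced size), roughly 120 000 voxels per subject, the
full 50-point regularization grid, and 6 evaluation folds. On one CPU the
complete suite runs in about ten minutes. Held-out performance on this
generator is mean Jaccard above 0.95 with per-subject volume errors of a
few percent; the suite's acceptance thresholds (0.85 and 10%) are the
protocol's, not tuned to the observed results.

## Known limitations

* The parcellation needs four detectable modes; volumes without brain in
  the field of view fail with a `ParcellationFailure` error rather than
  returning a guess.
* Cut points are flank inflections, not optimal thresholds (see above);
  each tissue interval leaks a few percent of its neighbours' tails.
  The classifier absorbs this through the geometric features.
* A linear decision function cannot carve out an *interior* level of the
  ordinal `hci` feature by intensity alone; separability relies on CSF
  being extreme (darkest tissue) and on the distance feature. Structures
  that are neither intensity- nor position-extreme would need a richer
  feature set or a nonlinear kernel, both out of scope.
* CSF-intensity structures adjacent to the ventricles (arachnoid cysts)
  are included in the mask — the documented failure mode.
* Volumes are reported on the 1 mm working grid; at clinical slice
  thicknesses the resampling itself moves volumes by up to a few percent.
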