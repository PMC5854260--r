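Package: ventvol
Title: Voxel-Wise Machine Learning Estimation of Brain Ventricular Volume
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments the lateral ventricles in structural T1-weighted brain
    MRI and quantifies their volume by voxel-wise classification. Four
    hand-crafted features are computed for every voxel (a histogram-derived
    intensity class, the distance to the scanner isocenter, a coarse
    block-position index, and a 26-neighbour relative-contrast count), an
    exhaustive cross-validated search ranks feature subsets, and a linear
    maximum-margin classifier trained on subject-grouped folds produces
    binary ventricle masks. Includes NIfTI input/output with isotropic
    resampling, volume and Jaccard evaluation of segmentations against
    manual masks, and a synthetic T1-like phantom generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    e1071,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
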