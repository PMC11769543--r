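Package: nephroseg
Title: Dual-Stage Kidney and Kidney-Tumor Detection and Segmentation for
    Contrast-Enhanced CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A coarse-to-fine framework for detecting and segmenting kidneys
    and kidney tumors in contrast-enhanced CT volumes. Stage one localizes the
    kidney region and hands expanded volumes of interest (VOIs) to stage two,
    a residual 3D UNet with attention-gated skip connections that segments
    tumors inside each VOI. The package ships the full preprocessing recipe
    (pooled percentile clipping, isotropic resampling, z-score normalization),
    a training-time augmentation set, CPU-trainable network implementations
    with a reverse-mode tape over BLAS kernels, an object-wise detection and
    size-stratified evaluation protocol (Dice, precision, volumetric distance,
    over-/under-segmentation ratios, sensitivity, false positives per
    patient), and a parametric CT phantom generator so the whole pipeline can
    be exercised without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
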