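Package: retinaHS
Title: Hyperspectral Retinal Imaging Analysis for Amyloid Status Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of retinal hyperspectral reflectance cubes for
    discriminating subjects with high brain amyloid-beta load from low-amyloid
    controls. Provides raw-to-reflectance calibration, inter-frame registration,
    spectral conditioning (log transform, Savitzky-Golay smoothing), systematic
    retinal sampling with difference-of-Gaussians vessel exclusion, the DROP-D
    orthogonal-projection discriminant producing per-subject hyperspectral (HS)
    scores, leave-one-out model-order selection, constituent decomposition of
    removed spectral axes, cross-grid model recalibration for a mouse imaging
    system, the associated biostatistics (t tests, odds ratios, Pearson
    correlations, ROC/AUC, Benjamini-Yekutieli FDR, repeated-measures ANOVA),
    and a synthetic-data generator with the spectral mixture structure the
    analysis assumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    signal,
    EBImage,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
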