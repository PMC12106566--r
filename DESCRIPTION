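Package: discage
Title: Effective Disc Age Modelling from Quantitative Lumbar Spine MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying normal, age-expected lumbar intervertebral
    disc degeneration from quantitative MRI. Implements noise-corrected
    single-exponential T2 relaxometry for multi-echo CPMG acquisitions,
    disc morphometry (volume, mid-sagittal area, width, height, bulge and
    wedge angle) from segmentation masks and vertebral fiducial markers,
    a frozen level-specific four-predictor linear model that maps nucleus
    pulposus T2 time, subject height, mid-sagittal disc area and disc volume
    to an "effective disc age", and the model-development workflow used to
    derive such models (all-possible-subsets regression, per-level ordinary
    least squares with standardized betas and variance inflation factors,
    and fivefold cross-validation). A synthetic-cohort and image-phantom
    generator with known ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    RNifti,
    stats,
    utils
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
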