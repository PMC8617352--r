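Package: beanspec
Title: Single-Bean Hyperspectral Prediction of Roasted-Coffee Aroma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and chemometric analysis pipeline for predicting
    volatile aroma compounds in single roasted coffee beans from
    short-wave-infrared hyperspectral images. Provides a synthetic
    bean/hypercube generator with known ground truth, ENVI raster input
    and output with dark/white reflectance calibration, bean
    segmentation and per-bean spectrum extraction, spectral
    pre-treatments (log(1/R), standard normal variate,
    Savitzky-Golay second derivative), PLS2 regression by NIPALS with
    segmented cross-validation and latent-variable selection, model
    quality metrics (R2, RMSECV, RPD), a roster of 50 coffee volatiles
    with chemical-class and odorant-series grouping, and a
    model-guided bean segregation trial with ANOVA/Tukey comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
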