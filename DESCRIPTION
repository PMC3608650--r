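Package: scenesim
Title: Simulation and Decoding Analyses for Good and Bad Scene-Category
    Exemplars
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to study how within-category variability of natural scene
    exemplars affects multi-voxel fMRI pattern decoding. Provides synthetic
    generators for category voxel prototypes, scene-like images with
    controllable within-category variance, and crowdsourced rating tables
    with check trials; Gabor-filter "form" and hue-saturation "color" feature
    spaces with covariance-eigenvalue variance summaries; a BOLD time-course
    simulator for block and event-related designs using a gamma hemodynamic
    response; linear-SVM leave-one-run-out decoding with per-volume
    classification and majority voting; univariate GLM percent-signal-change
    analyses including a block-halves repetition-suppression variant; and
    rating quality control based on check-trial discount scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
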