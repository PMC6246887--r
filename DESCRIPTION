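Package: filmseg
Title: Event-Boundary Sensitivity Analysis for Naturalistic fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether region-of-interest fMRI activity during
    continuous film viewing is sensitive and specific to subjectively annotated
    event boundaries. Builds consensus boundaries from independent observers'
    keypress logs (reaction-time correction, two-pass within-TR merging,
    observer-count thresholding, salience binning), estimates boundary-evoked
    BOLD amplitudes with hemodynamic stick-function GLMs and FIR deconvolution,
    assesses significance with duration-shuffling permutation nulls, computes
    perceptual-change covariates from film frames and audio (IMED, IMNCC,
    histogram and luminance differences, spectral measures), fits crossed
    random-effects mixed models of boundary salience, segments multi-voxel
    cortical patterns with an ordered-event hidden Markov model, and detects
    events in a data-driven manner by greedy residual minimisation. A synthetic
    data generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    lme4,
    lmerTest,
    RNifti,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
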