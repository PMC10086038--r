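Package: presaccade
Title: Isolating Pre-Saccadic Visually Evoked Activity in MEG Planar Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for isolating visually evoked magnetoencephalography (MEG)
    activity that precedes saccade onset. Saccade-locked combined planar
    gradients from a condition containing both a saccade and a visual stimulus
    are modelled per sensor site as a weighted linear combination of
    Saccade-only and Stimulus-only condition templates; the residual traces are
    tested against zero with spatiotemporal cluster-permutation statistics.
    Includes adaptive velocity-threshold saccade detection for eye-tracking
    data, kernel-density surrogate resampling of saccade onsets for fixation
    trials, hemispheric lateralization contrasts with chi-square and Bayes
    factor proportion tests, and a synthetic session generator that produces
    MEG, gaze and photodiode recordings with full ground truth so that every
    stage of the pipeline can be validated against a known answer.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
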