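Package: neurofocus
Title: Decoding Focus Dynamics from Wearable EEG and Modeling the Effect of Audio
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying how background audio affects
    human focus using a four-channel EEG headband. Provides a synthetic-data
    generator that plants a known alpha-suppression/beta-enhancement coupling
    between a latent focus profile and band-limited EEG, preprocessing
    (band-pass/notch filtering, 5 s sliding-window segmentation, motion gating,
    blink counting), a 124-feature spectral/temporal battery per segment,
    per-participant ensemble random-forest focus decoding at 5 Hz,
    condition-level statistics (repeated-measures ANOVA, Holm-corrected paired
    post hocs, and a permutation run-length-corrected per-second time-series
    test), short-time audio decomposition aggregated to 136 sound properties
    per 30 s window, and a PCA + backward-elimination linear model that
    predicts focus from audio properties alone with song-stratified
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    ranger,
    pROC,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
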