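Package: beamspike
Title: Beamformer and Dipole-Scan Validation for Epileptic Spike Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Source-localization validation pipeline for interictal epileptic
    spikes in EEG, MEG and combined MEG/EEG. Provides analytic concentric-sphere
    forward models (multilayer series EEG potentials, Sarvas MEG fields), a
    seeded multi-trial spike and somatosensory-evoked data simulator,
    preprocessing (zero-phase Butterworth filtering, trial averaging,
    rising-flank time-point selection, noise normalization for combined
    modalities), unit-noise-gain and event-related beamformers with
    generalized-eigenvalue optimal orientation, goodness-of-fit dipole scanning
    with truncated-SVD leadfield reduction, SEP/SEF skull-conductivity
    calibration, and resection-referenced evaluation metrics (resection
    distance, relative power) swept over covariance regularization strengths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
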