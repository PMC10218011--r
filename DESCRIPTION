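Package: boldflow
Title: Block-Design and Resting-State BOLD Analysis for Motion-Sensitive Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for periodic block-design fMRI and resting-state
    functional connectivity in motion-sensitive cortical areas (MT+, V6, PIVC,
    V1). Implements framewise-displacement motion quality control with series
    exclusion and segmentation, a gamma-variate hemodynamic response model
    calibrated against the canonical 64-degree fundamental phase, voxelwise
    ordinary-least-squares GLM with motion and Fourier high-pass regressors,
    V1-seed lagged-correlation masking, ROI spectral signal-to-noise and phase
    statistics with circular averaging, and 7x7 ROI-pair connectivity with
    aggregate-subject significance and between-group tests. A synthetic BOLD
    generator reproduces the acquisition structure (21 s alternating blocks at
    TR 3 s with dummy scans, AR(1) plus drift noise, head-motion spikes, and
    imposed resting correlations) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
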