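Package: fgdae
Title: Fully-Gated Denoising Autoencoder for ECG Artifact Removal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removal of baseline wander, muscle artifact and electrode motion
    noise from single-lead electrocardiogram segments with a fully gated
    denoising autoencoder built from self-organized operational neural network
    (self-ONN) layers. Provides the gated layer primitives (polynomial self-ONN
    convolutions, gated transpose convolutions, channel attention, residual
    gates, instance normalization) with hand-written exact gradients, the
    U-Net-style encoder/decoder assembly with exact parameter accounting, the
    composite reconstruction/gradient/morphology/sparsity training objective,
    a random-mixed-noise benchmark builder for QT Database and Noise Stress
    Test Database style recordings (including a minimal WFDB reader), seven
    signal-quality metrics with stratified reporting and paired Wilcoxon
    testing, classical zero-phase high-pass filter baselines, and a synthetic
    ECG and artifact generator so the full pipeline runs with no data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
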