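Package: thetalink
Title: Linking Hippocampal Theta Oscillations in LFPs to Multineuronal
    Membrane Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline relating hippocampal CA1 local field
    potential (LFP) theta oscillations (3-10 Hz) to the membrane
    potentials (Vm) of up to three simultaneously patch-clamped pyramidal
    cells. Provides Morlet-wavelet spectrograms, surrogate-calibrated
    theta-period detection, Dice-overlap and cross-correlogram coupling
    statistics, circular spike-phase statistics (Rayleigh, Kuiper),
    Jonckheere-Terpstra trend tests, a synthetic LFP/Vm/spike generator
    with known ground truth, and an encoder-decoder convolutional network
    that predicts the theta-band LFP waveform from theta-band Vm traces,
    validated against within-cell segment-shuffle controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    rhdf5,
    signal,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
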