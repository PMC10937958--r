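Package: lfpstate
Title: Multi-Structure LFP Brain-State Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of multichannel local field potential (LFP)
    recordings for pharmacological brain-state characterization: bipolar
    derivation, Welch spectrograms, separation of rhythmic from arrhythmic
    (1/f) spectral components by irregular resampling, parametric Gaussian
    peak detection for gamma and high-frequency oscillations, cross-structure
    phase coupling quantified by the von Mises concentration kappa,
    permutation-entropy signal complexity, global brain-state similarity via
    correlation of concatenated fractal-normalized spectra, open-field
    locomotion-bout metrics from pose tracks, and hierarchical permutation
    statistics for nested animal/session designs. Includes a synthetic-data
    generator with ground-truth ledgers for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
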