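Package: aleewr
Title: EEG Schizophrenia Screening via Empirical Wavelet Reconstruction and Cepstral Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing and classification pipeline for resting-state
    multichannel EEG screening of schizophrenia. Implements FastICA artefact
    removal, automated log-energy-based empirical wavelet reconstruction
    (adaptive Meyer-type filter banks with data-driven spectral boundaries and
    log-energy mode selection), cepstral Hjorth descriptors (activity, mobility,
    complexity) per channel, one-way ANOVA F-statistic feature ranking, and
    k-nearest-neighbour classification under repeated stratified k-fold
    cross-validation. Includes a seeded two-class synthetic EEG generator with
    ground-truth blink artefacts, a minimal EDF reader/writer, and delimited
    text input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    class,
    optparse,
    jsonlite
Config/testthat/edition: 3
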