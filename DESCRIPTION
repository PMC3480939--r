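Package: aswtd
Title: Adaptive Stationary Wavelet Artefact Removal for Self-Paced EEG
    Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects and removes ocular and muscle artefacts from
    multichannel electroencephalogram (EEG) recordings using a five-level
    stationary wavelet transform (Coiflet-3, a trous algorithm) combined
    with an adaptive per-level thresholding rule that shrinks wavelet
    thresholds until the residual coefficient power matches resting-state
    reference levels.  Ships the standard comparators (fixed universal
    and reference-derived wavelet thresholds, SURE-optimal soft
    thresholding, and an AMUSE blind-source-separation path with
    automatic artefact-component rejection), a semi-simulated EEG
    benchmark generator (band-limited artefacts mixed into surrogate
    clean EEG at controlled signal-to-noise ratio), a pseudo-online
    self-paced brain-computer interface pipeline (bipolar derivations,
    FFT band-power features, stepwise linear discriminant analysis,
    debounce and dwell gating), and the associated performance metrics
    (mean squared error, spectral distortion, true positive rate and
    time-normalised false positive rate).
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    MASS,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
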