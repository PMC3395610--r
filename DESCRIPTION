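Package: eodcoding
Title: Envelope Coding of Electric Organ Discharge Scenes in Weakly Electric Fish
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the composite electric organ discharge (EOD) signal
    received by a weakly electric fish from stationary and moving
    conspecifics, extracts its first (beat) and second (motion) envelopes
    by Hilbert-transform methods, and quantifies how leaky
    integrate-and-fire electroreceptor afferents with dynamic thresholds
    (P-units) encode beats and motion. Moving neighbours are modelled as
    sinusoidal EODs whose amplitudes fluctuate as scaled
    Ornstein-Uhlenbeck processes. Provides spectral characterization
    (Welch power spectra, spectrograms, autocorrelation with
    correlation-time fitting, beat-peak metrics, envelope period
    statistics), single-unit and heterogeneous-population P-unit
    simulation with firing-probability calibration, and coding readouts
    (cross-spectra, magnitude-squared coherence, Gaussian-channel mutual
    information rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
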