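Package: photodrive
Title: Photic Driving, Alpha Entrainment and Topographic Matching Pursuit
    Analysis for MEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for intermittent photic stimulation (IPS)
    experiments on magnetoencephalography recordings under scotopic,
    rod-dominated viewing. Implements zero-phase Butterworth preprocessing
    with event-anchored train averaging, FFT spectra with a two-rule alpha
    frequency-entrainment classifier and alpha peak ratio statistics,
    Topographic Matching Pursuit (multichannel Gabor-atom fitting with a
    shared scale/translation/modulation and per-channel amplitudes and
    phases), correlation-coefficient sequences with engagement/plateau/
    disengagement segmentation and good/moderate/weak response
    classification, Hilbert-envelope on-/off-response detection with group
    statistics, and a synthetic whole-head MEG session generator emulating
    the stimulation protocol (20 frequency blocks of 30 trains of 40
    flashes, locked to the individual alpha frequency) with ground-truth
    labels for every downstream classifier.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
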