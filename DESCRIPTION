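Package: earval
Title: Validation Toolkit for Ear-Level EEG Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline analysis engine and synthetic-data generator for
    validating ear-EEG acquisition systems without hardware or subjects.
    Implements the nine standard EEG validation paradigms (resting state,
    alpha block, 40 Hz auditory steady-state response, 10 Hz steady-state
    visual evoked potential, transient auditory and visual evoked
    potentials, auditory and visual oddball, electrooculography), a
    marker-synchronized epoching and filtering chain, Welch and short-time
    Fourier spectral estimators with narrowband signal-to-noise metrics,
    conductive-phantom bench calculations (mixture recipes, conductivity,
    impedance quality control, noise floor, simulated-signal SNR,
    integrity trends), and a trigger-latency estimator. A seeded simulator
    produces paradigm sessions and phantom recordings with known ground
    truth for end-to-end testing of the analysis chain.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
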