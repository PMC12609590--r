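Package: sdoftf
Title: Motion-Artifact Removal from Arterial Pulse Signals by an SDOF
    Time-Frequency Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for simulating and cleaning arterial pulse waveforms
    measured at rest with tactile or photoplethysmography (PPG) sensors.
    The tissue-contact-sensor stack is modelled as a base-excited
    single-degree-of-freedom (SDOF) oscillator whose mass, damping and
    stiffness drift with baseline motion, turning motion artifacts into
    multiplicative distortion riding on every pulse harmonic.  A
    time-frequency pipeline built on Hilbert vibration decomposition
    separates the harmonics, tracks their instant amplitude, frequency
    and initial phase, reconstructs the pulse free of artifacts, and
    reports arterial pulse waveform indices, heart rate, respiration
    parameters, and a partition of heart-rate variability into
    respiratory and other physiological components.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
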