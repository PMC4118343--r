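Package: breathclass
Title: Respiration Rate and Breathing-Pattern Classification from Chest
    Accelerometry
Version: 0.1.0
Authors@R:
    person("Signal", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for wearable respiratory monitoring from a chest-mounted
    triaxial accelerometer: six-position least-squares sensor calibration,
    zero-phase Butterworth filtering, measured-sampling-rate estimation with
    rational-fraction anti-aliased resampling, cross-correlation
    synchronization against a reference channel, and respiration-rate
    estimation by gated local-maxima counting. Windowed features (mean,
    standard deviation, energy, inter-axis correlation, peak counts and
    approximate entropy) feed a hierarchical support vector machine that
    classifies six breathing patterns (normal, bradypnea, tachypnea,
    Cheyne-Stokes, Kussmaul and Biot's respiration). A seeded simulator
    generates labelled breath waveforms and accelerometer recordings
    emulating a multi-subject trial protocol so the whole pipeline is
    testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    quadprog,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
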