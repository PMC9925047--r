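Package: pcfkit
Title: Simulation and Analysis of Patch-Clamp Fluorometry Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying voltage-sensor gating with simultaneous
    current and fluorescence recordings (patch-clamp fluorometry), built
    around the human voltage-gated proton channel. Provides a Q-matrix
    (master-equation) simulator for arbitrary Markov gating schemes with
    voltage-dependent rate constants, per-state fluorescence weights and a
    whole-cell current observable; the complete trace-analysis pipeline
    (conductance extraction, Boltzmann G-V/F-V fits, mono- and
    bi-exponential kinetics, tau-voltage fits, dF/F0 normalization);
    emission-spectrum background subtraction, peak finding and
    Anap/mCherry ratiometry with the associated summary statistics; and a
    deterministic synthetic-data generator that emulates the acquisition
    chain (20 kHz sampling, 5 kHz Bessel anti-alias filtering, 10-25 Hz
    camera frames) so every analysis stage can be exercised without raw
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    signal,
    yaml,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
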