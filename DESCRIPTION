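Package: retinaresp
Title: Retinal Light-Response Analysis from Spike Trains, ERG Waveforms and
    Optomotor Thresholds
Version: 0.1.0
Authors@R:
    person("Retina", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of retinal electrophysiology
    experiments: band-pass filtering and threshold-crossing spike detection on
    extracellular traces, peri-stimulus time histogram (PSTH) construction and
    parameterization (response amplitude, time to peak, response duration),
    ON/OFF ganglion-cell classification via the bias index, stimulus-series
    analysis (spot size, intensity, flicker) with repeated-measures two-way
    ANOVA group comparison, electroretinogram (ERG) a-/b-wave metrics and
    flicker-fusion estimation, and optomotor contrast-sensitivity computation
    from Michelson contrast thresholds. Includes an inhomogeneous-Poisson
    synthetic-data generator with known ground truth so every stage is
    testable without recordings, plus a file-based pipeline and command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
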