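Package: smoscreen
Title: Flow-Cytometry Analysis of a Smoothened Activation Sensor Screen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for FACS-based high-throughput screens built
    around a fluorescent Smoothened (Smo) activation sensor expressed in a
    clonal Drosophila S2 cell line. Provides a synthetic event-level flow
    cytometry data generator with known ground truth (log-normal off/on
    fluorescence states, per-cell log-normal activation thresholds, debris
    scatter populations, compound effects on a 384-well layout), robust
    ellipsoidal scatter gating with a gated-fraction QC rule, per-well median
    fluorescence and dual-control normalized response statistics,
    target-class aggregation with cluster-size cutoffs and hit calling,
    two-component mixture modelling of bimodal fluorescence histograms with
    responder-fraction estimation, and recovery of the per-cell activation
    threshold distribution from dilution series. Includes readers and
    writers for FCS 3.0 event files, a long-format CSV event dialect, plate
    maps and compound annotation tables, plus an end-to-end screen pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
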