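Package: trpkit
Title: Calcium-Imaging Responder Analysis and TRP Channel Expression
    Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping transient receptor potential (TRP) channel
    expression and function across placental development: Fura-2
    ratiometric calibration of dual-wavelength fluorescence traces to
    absolute intracellular calcium, per-cell agonist responder
    classification from amplitude and derivative criteria, aggregation of
    responder calls into per-experiment and pooled cohort summaries with
    standard group comparisons, qRT-PCR relative quantification (delta-Ct
    against the geometric mean of housekeeping genes, fold changes,
    expression categories relative to Trpm7), and RPKM normalization with
    row-centered log2 heatmap matrices. A seeded synthetic-data generator
    produces ground-truth-labeled traces, Ct tables and count matrices so
    every stage is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
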