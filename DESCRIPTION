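Package: promoterflux
Title: Absolute Promoter Activity from Single-Cell Plasmid and Transcript Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies fluorescent spots in bacterial microscopy images
    (2D Gaussian fitting with constant background), calibrates the intensity
    of a single labelled molecule from equidistant peaks in spot-intensity
    histograms, counts plasmids and mRNA per cell, and infers promoter
    activity in absolute units (RNA polymerases per second per DNA copy)
    using a fitted mRNA degradation rate. Includes a stochastic simulator of
    plasmid copy-number distributions under tunable partitioning and
    replication-control feedback, a two-state (telegraph) transcription
    simulator, and a seeded synthetic-data generator that produces images,
    masks and count tables with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    tiff,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
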