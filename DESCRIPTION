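Package: coraldyn
Title: Quantitative Time-Lapse Analysis of Coral Tissue Response
Version: 0.1.0
Authors@R:
    person("Coral", "Dynamics Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for high-frequency time-lapse analysis of coral colonies
    under environmental stress. Provides a synthetic time-lapse generator with
    known ground truth, lossless image-series input/output, statistics-based
    white-balance correction, k-means dominant-color extraction with stage
    segmentation and ternary trajectories, Pearson-correlation morphology
    tracking of individual polyps with change-point detection, and recurrence
    plots with recurrence quantification analysis (recurrence rate,
    determinism, longest diagonal line, entropy, laminarity, trapping time),
    including before/after segmented statistics. A pipeline orchestrator and
    command-line entry point run the full analysis from a single config file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
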