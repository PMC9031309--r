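Package: screenquant
Title: Scoring and Quantification for Yeast Deletion-Library Modifier Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for arrayed yeast over-expression modifier
    screens and their follow-up assays. Scores colony-size screens with
    per-plate Z-normalization and the change-from-vector (deltaV) statistic,
    calls and aggregates candidate gene deletions, and partitions candidate
    sets into Venn regions. Quantifies single-cell fluorescence from
    multi-channel micrographs (whole-cell GFP, cell-surface and vacuole
    compartment means, PM/vacuole ratios), summarizes populations by median
    with bootstrap confidence intervals, and splits bimodal expression
    populations with a log-scale mixture model. Performs immunoblot
    densitometry (background subtraction, loading-control normalization,
    cycloheximide-chase percent-remaining kinetics, cleavage ratios) and
    relative transcript quantification by the 2^-ddCt method. Ships seeded
    synthetic-data generators for all four modalities with planted ground
    truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    stats,
    utils,
    mclust,
    withr,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
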