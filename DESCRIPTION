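Package: oncopanel
Title: QC, Normalization, Signature Scoring and Concordance for Targeted
    Oncology Probe Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for targeted probe-based RNA
    counting panels assayed on large tissue-microarray cohorts: probe-count
    quality control (sequencing-depth and relative-standard-deviation
    filters, universal-RNA correlation and housekeeping-gene sample-quality
    calibration), negative-control background subtraction, adjusted
    counts-per-million with upper-quartile normalization, per-gene Z-score
    gene-signature scoring and argmax molecular-subtype assignment,
    expression-amplicon calling over genomic neighborhoods, and
    mRNA-protein / cross-platform concordance statistics. Includes a
    synthetic-cohort generator with planted ground truth so every stage is
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
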