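Package: fusemble
Title: Ensemble Integration, Filtering and Benchmarking of RNA-Seq Gene Fusion Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes the native output of five RNA-seq gene fusion callers
    (Arriba, CICERO, deFuse, FusionCatcher and STAR-Fusion) into one
    standardized call table, merges equivalent calls into fusion events with a
    per-caller evidence trail, selects consensus call sets by k-of-n caller
    agreement, applies a configurable artifact filter cascade (read support
    and confidence thresholds, read-through, reading-frame and splice-site
    rules, gene blacklist, promiscuous-gene removal with a clinical whitelist
    rescue), and benchmarks any call set against a truth list of previously
    confirmed rearrangements with sensitivity, precision and F1. A synthetic
    cohort simulator emits caller-native files, toy annotation and truth sets
    so every stage is testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
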