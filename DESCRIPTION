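Package: prebsr
Title: Probe Region Expression Estimation from RNA-Seq for Microarray
    Comparability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates gene and probe-set expression from RNA-seq reads
    restricted to microarray probe regions. Read counts over probe regions
    are converted to expression estimates with a Poisson likelihood under a
    conjugate gamma prior whose hyperparameters are set by empirical Bayes,
    then summarised with microarray-style algorithms (quantile
    normalisation followed by median-polish or probe-variance-weighted
    summarisation), skipping background correction. Includes an RPKM
    read-counting baseline, cross-platform comparison machinery
    (top-fraction filtering, correlation tests, fold-change agreement,
    extreme quantile normalisation, signature-based retrieval) and a
    synthetic paired RNA-seq/microarray data generator with known ground
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
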