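Package: guidecall
Title: Mutation-Aware Guide RNA Detection and Assignment for Single-Cell CRISPR Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, annotates and assigns intact and mutant CRISPR guide RNAs
    to single cells from barcode- and UMI-tagged alignments of targeted guide
    libraries. Collapses reads sharing a (cell barcode, UMI) pair into consensus
    molecules, itemizes deviations from the designed cassette via alignment
    CIGARs, names guide variants, classifies likely mutation sources, and
    assigns guides to cells with fixed or Gaussian-mixture UMI thresholds.
    A separate mode detects Cas9-induced deletions spanning predicted cutsites
    in matched transcriptome alignments. Includes a ground-truthed synthetic
    screen generator with downsampling and concordance utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    rtracklayer,
    Matrix,
    mclust,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
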