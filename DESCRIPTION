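Package: imprintscan
Title: Imprinted-Gene Calling and DNA-Methylation Analysis for Endosperm
    Reciprocal Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies genomically imprinted genes from allele-specific
    RNA-seq read counts in endosperm of reciprocal crosses, using a chi-square
    test of gene-level maternal/paternal counts against the triploid-endosperm
    2m:1p dosage null with Benjamini-Hochberg correction and low/high
    stringency MEG/PEG classification.  Also detects genomic clusters of
    imprinted transcripts, computes bulk and gene-anchored bisulfite
    methylation profiles, calls embryo/endosperm differentially methylated
    regions (DMRs) by a sliding-window Fisher exact test with merging, and
    tests the association between imprinted genes and DMR occurrence.  A
    synthetic-data generator with planted ground truth makes every stage
    testable without external sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
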