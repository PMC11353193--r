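Package: ilseq
Title: Dual-Genome RNA-Seq Analysis for Introgression Lines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for bulk RNA-seq of introgression lines
    carrying wild-relative chromosomal segments, where reads must first be
    assigned to their genome of origin. Implements competitive two-genome
    read partitioning from SAM alignment scores (Slyc/Penn/Ambi subsets),
    gene-level EM quantification of multi-mapping fragments, TMM
    normalization with negative-binomial quasi-likelihood F-tests for
    differential expression, hypergeometric pathway over-representation in
    separate-species and merged-gene-set modes, and relative qPCR
    quantification by the 2^-delta-delta-Ct method. A seeded synthetic-data
    generator emulates the full study design (diverged genome pair,
    introgressed intervals, planted differential expression, alignment
    bundles, Ct tables) for validation and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    ggplot2,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    limma,
    Rsamtools,
    rtracklayer
Config/testthat/edition: 3
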