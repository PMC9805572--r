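Package: ampliconcnv
Title: Germline CNV Calling from Amplicon-Based Targeted Resequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects germline copy-number variants (CNVs) in amplicon-based
    (HaloPlex-style) targeted resequencing panels without matched controls.
    Reads are assigned to amplicons by exact coordinate matching, counts are
    GC-corrected and normalized per sample, technical variance is removed by
    principal component analysis (or an equivalent classical
    multidimensional-scaling fast path), leave-one-out log2 coverage ratios
    are segmented with circular binary segmentation, and candidate segments
    are filtered by amplicon count, standard deviation and an
    amplicon-overlap-weighted re-scoring step. Downstream utilities provide
    optimal univariate k-means clustering with BIC model selection for
    false-positive triage, exact binomial performance metrics, annotation
    against target exon regions, and per-segment visualization. A seeded
    simulator generates amplicon designs, spiked count matrices and miniature
    BAM fixtures for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    data.table,
    Rsamtools,
    Biostrings,
    GenomicAlignments,
    IRanges,
    GenomicRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
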