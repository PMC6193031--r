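Package: multiMark
Title: Multivalent Chromatin-State Classification and Germline Gene-Set
    Analysis for Gamete Epigenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of gamete and embryo epigenome profiling in
    C. elegans: autosome-referenced scaling of ChIP-seq coverage tracks,
    gene-body and promoter signal quantification, log2/z-score normalization
    with a percentile baseline for broad repressive marks, quadrant and
    multivalency chromatin-state classification of genes by H3K4me3,
    H3K36me3 and H3K27me3, RPKM and FDR rule-based germline gene-set
    construction backed by a negative-binomial two-group test, MNase-seq
    tiled-window nucleosome occupancy with low-coverage exclusion and
    autosome-vs-X summaries, and hypergeometric overlap plus Mann-Whitney
    shift statistics. A fully seeded synthetic-data generator with planted
    ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
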