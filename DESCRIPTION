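Package: tadlink
Title: TAD-Constrained Integration of ATAC-seq and RNA-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of chromatin accessibility (ATAC-seq)
    and gene expression (RNA-seq) across sample groups. Provides consensus
    peak-set construction and shared/unique (Venn) classification, size
    factor and variance-stabilizing normalization of count matrices,
    a negative-binomial Wald test for differential features with
    Benjamini-Hochberg correction, peak-to-gene correlation linking
    constrained to topologically associating domains (TADs) with signed
    link classification and genomic-context summaries, position weight
    matrix motif scanning with exact score-distribution thresholds and
    hypergeometric enrichment, and a fully seeded synthetic multi-omics
    generator that plants known links, differential genes and motif
    instances so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ATACSeq, RNASeq, Epigenetics, GeneRegulation, Software
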