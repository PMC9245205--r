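Package: heteroseq
Title: Dominance, Allele-Specific Expression and Variant Impact Analysis
    for Hybrid-Parent Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of heterosis in hybrid/parent trios from gene-level
    RNA-seq read counts. Provides negative-binomial Wald differential
    expression with median-of-ratios normalization, classification of
    hybrid expression inheritance mode (additive, partial dominance,
    dominance, over-dominance) from the dominance-to-additivity ratio Hp,
    gene-level allele-specific expression calling from parent-distinguishing
    SNPs with a negative-binomial GLM, cross-tissue allele-specific
    expression patterns, resampling overlap enrichment between gene sets,
    hypergeometric term over-representation, variant hard filtering and a
    minimal variant consequence/impact annotator, plus a synthetic-data
    generator with a ground-truth table so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
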