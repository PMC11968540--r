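Package: sveqtl
Title: Structural-Variant Genotype Concordance and cis-eQTL Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the impact of structural variants (SVs) on gene
    expression in inbred crop populations. Implements per-variant dual-perspective
    (REF/ALT allele) F1 genotype-concordance scoring of short-read SV genotypes
    against a long-read truth set, post-calling variant quality control,
    quantification-concordance screening with a permutation enrichment test, a
    from-scratch cis-eQTL linear-model scan with inverse normal transformation
    and principal-component covariates, transposable-element family assignment
    by best local-alignment hit, and effect-size summaries (effect vs allele
    frequency, insertion vs deletion effects, variance explained). A synthetic
    cohort generator emulates the matched long-read/short-read study design of
    highly inbred lines and provides ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    readr
Config/testthat/edition: 3
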