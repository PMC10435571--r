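Package: regulomine
Title: Mining GATA1-Driven Regulatory Sites in Blood-Group Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for mining transcription-factor-driven
    regulatory sites in blood-group genes from ChIP-seq peak sets:
    replicate merging and cross-dataset consensus peak intersection,
    position-weight-matrix motif localization with JASPAR-style relative
    scores and FIMO-style exact p-values, annotation of candidate sites to
    genes, and quantification of motif disruption by single-nucleotide
    variants. Companion cohort-genetics tools estimate two-locus haplotype
    frequencies (double-heterozygote rule and EM), linkage-disequilibrium
    statistics D' and r-squared, and genotype-dose associations with
    erythrocyte expression readouts (geometric mean fluorescence intensity,
    delta-delta-Ct) via one-way ANOVA with Bonferroni post-hoc tests and
    ordinary least squares regression. A synthetic-data module generates
    complete ground-truth input bundles so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stringr,
    tibble,
    tidyr,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
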