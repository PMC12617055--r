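Package: sexbiasr
Title: Sex-Biased Gene Expression, Chromosome Enrichment, Expression
    Divergence and Rank-Rank Concordance for RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for characterising sex-biased gene
    expression from bulk RNA-seq count matrices across species, tissues and
    sex-chromosome systems. Provides count filtering, median-of-ratios size
    factors and TPM normalisation, negative-binomial GLM Wald tests for sex
    bias with Benjamini-Hochberg correction, chromosome-level enrichment and
    feminisation/masculinisation summaries (Fisher exact and rank tests),
    the delta-x expression-divergence statistic for putative directional
    selection, threshold-free rank-rank hypergeometric overlap (RRHO)
    concordance maps with Benjamini-Yekutieli correction, and a
    negative-binomial simulator that emits ground truth for end-to-end
    recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    DESeq2,
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
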