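Package: hybridmode
Title: Inheritance-Mode Analysis of Gene Expression in Wild x Domesticated Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for two-channel reference-design
    microarray experiments comparing pure wild, pure domesticated, and F1
    hybrid genotypes. Provides a synthetic-data generator for reference-design
    scans with known per-gene genotype effects, MA-based LOWESS preprocessing
    with intensity/flag filtering, group-pairwise differential expression
    (one-way ANOVA, Tukey HSD, Benjamini-Hochberg), classification of each
    differentially expressed transcript's mode of inheritance in the hybrid
    (additive, dominant, recessive, resembling-additive via genotype-dose
    regression, or no effect), concordance analysis across two wild reference
    groups, and consolidated reporting with clustering and PCA diagnostics.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
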