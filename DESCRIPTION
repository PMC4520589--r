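Package: rhizorank
Title: Rank-Based Detection of Rhizosphere-Enriched Taxa in Microbial
    Community Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for amplicon-survey community analysis of
    paired whole-soil and rhizosphere samples from blocked factorial field
    designs. Provides OTU-table input/output (classic TSV and BIOM-JSON),
    minimum-count filtering, taxonomic collapsing, rarefaction by subsampling
    without replacement, alpha-diversity (richness, Shannon's H', Pielou
    evenness) with full-factorial ANOVA and interaction pruning, Bray-Curtis
    beta-diversity with PERMANOVA and NMDS ordination, and a paired
    rank-abundance statistic (delta rank) with stratified bootstrap confidence
    intervals and hierarchical drill-down from orders to families and genera.
    A Dirichlet-multinomial community simulator reproduces the statistical
    structure of the supported designs so every stage is testable without
    external sequence data.
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
    permute,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    biomformat,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
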