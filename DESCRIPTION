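Package: clanova
Title: Taxonomic Diversity and Variance Partitioning of Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the evolutionary diversity of an aligned protein
    family along a taxonomic lineage. Computes pairwise p-distances with
    pairwise or complete gap deletion, per-taxon diversity summaries
    (mean and SD of per-sequence average p-distances at every rank),
    partitions diversity at each taxonomy bifurcation into inter-clan and
    intra-clan variance components with unequal-size model II (random
    effects) ANOVA, and builds neighbor-joining trees with alignment-column
    bootstrap supports. Includes a seeded simulator of protein families
    evolving over a configurable taxonomy under a 20-state equal-rates
    substitution model, with optional horizontal-transfer events, so the
    whole pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
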