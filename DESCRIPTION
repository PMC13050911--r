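Package: pollenet
Title: Pollen Microbiome Diversity, Co-Occurrence Networks and Core-Taxon
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for analysing pollen (and other
    low-biomass plant-associated) microbial communities sampled under
    factorial pollination-exclusion designs.  Provides genus/OTU count-table
    handling, rarefaction and alpha diversity (bias-corrected Chao1,
    Shannon, Faith's phylogenetic diversity), Bray-Curtis beta diversity
    with PERMANOVA, Spearman co-occurrence and cross-domain
    (bacteria-fungi) network inference with Benjamini-Hochberg FDR gating,
    modularity-based module detection, keystone (core) taxon identification
    by degree and betweenness centrality, core-taxon community-contribution
    statistics, pollen remaining-rate (insect visitation) analysis with
    bootstrap species-level Spearman correlation and Cohen's d, and a
    synthetic-data generator with planted correlation blocks and core taxa
    so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    vegan,
    igraph,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    optparse
Config/testthat/edition: 3
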