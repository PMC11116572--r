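Package: soilconet
Title: Pollution Indices, Diversity and Bacterial-Fungal Co-Occurrence
    Networks for Heavy-Metal Soil Microbiomes
Version: 0.1.0
Authors@R:
    person("soilconet", "developers", email = "soilconet@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of amplicon (16S/ITS) surveys of
    heavy-metal-contaminated agricultural soils: contamination factors and
    the pollution load index with pollution classes; alpha diversity
    (Good's coverage, bias-corrected Chao1, Gini-Simpson), Bray-Curtis
    ordination, ANOSIM and Mann-Whitney group tests; Spearman
    environment-taxon association heatmaps with Benjamini-Hochberg
    correction and Mantel tests; cross-domain bacterial-fungal
    co-occurrence networks with topology summaries, greedy-modularity
    module detection, Zi-Pi connectivity and keystone-taxon
    classification. Includes a latent Gaussian copula community simulator
    with planted modules, hubs, connectors and metal responders, used for
    ground-truth recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
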