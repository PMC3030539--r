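Package: metcornet
Title: Metabolomic Correlation Networks, DPClus Graph Clustering and
    Pathway-Enrichment Assessment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for metabolite profile matrices: log2
    transformation, rank-product differential abundance testing with
    permutation-based false discovery estimation, PCA, Spearman
    correlation networks with local false-discovery-rate edge calling and
    Fisher Z differential correlation between conditions, threshold
    selection by graph-topology sweeps against randomized-data nulls, a
    from-scratch implementation of the DPClus density/cluster-property
    graph clustering algorithm (overlapping mode), and pathway
    over-representation assessment of clusters via Fisher's exact tests
    and a permutation-null S-value. Includes a synthetic-data generator
    that plants latent-factor correlation modules, genotype mean shifts
    and heavy-tailed outliers so every stage is testable against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
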