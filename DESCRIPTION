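Package: hemaCCC
Title: Cell-Cell Communication Network Analysis of the Hematopoietic System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs and analyses directional cell-cell communication
    networks between phenotypically defined hematopoietic cell types from
    gene expression data and a curated ligand-receptor interaction table.
    Provides differential over-expression calling (one-sided Wilcoxon with
    Benjamini-Hochberg control and ROC-guided threshold selection), bipartite
    network construction with an aggregate "Others" population, structure
    analysis of the ligand production and binding networks (Jaccard/Ward
    clustering with silhouette-selected module number, Dhillon spectral
    co-clustering), frequency-weighted potential of apparent competition,
    an OR-gate Monte-Carlo compartmentalization model of ligand reach,
    mixed-model signed one-tail p-values for in vitro ligand effects with a
    decision-table functional classifier, hypergeometric enrichment Z-scores,
    and weighted feedback-network construction. A synthetic-data module
    generates expression matrices, interaction tables and culture counts with
    planted structure so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    cluster,
    nlme,
    igraph,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ccc-network.R'
    'compartment-model.R'
    'competition.R'
    'diffexpr.R'
    'evaluation.R'
    'ligand-effects.R'
    'lr-database.R'
    'pipeline.R'
    'structure.R'
    'synthetic-data.R'
    'utils.R'
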