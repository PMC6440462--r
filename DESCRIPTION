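Package: mbstates
Title: Robust Identification of Microbiome Community States
Version: 0.1.0
Authors@R: person("mbstates", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated, internally validated identification of microbiome
    community states from taxon abundance tables.  A grid of clustering
    solutions (partitioning around medoids and UPGMA hierarchical
    clustering, five abundance-based beta-diversity dissimilarities,
    k = 2..10) is screened by a three-criterion robustness assessment:
    average silhouette width, prediction strength, and bootstrap cluster
    stability scored by Jaccard set similarity.  Includes BIOM/TSV input,
    taxa dominance filtering and taxonomic aggregation, assessment and
    ordination graphics, longitudinal state-sequence diagrams, a
    Dirichlet-multinomial synthetic-data generator with planted states,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    biomformat,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    cluster,
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
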