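Package: connectoclass
Title: Connectome-Based Classification of Depression with Graph Metrics
    and Support Vector Machines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Graph-theoretic analysis and classification of structural
    brain connectomes. Converts weighted fiber-count connectivity
    matrices over the 68-region bilateral Desikan-Killiany cortical
    atlas into fixed-density binarized graphs, computes nine global
    graph metrics (assortativity, flow coefficients, betweenness,
    efficiency, modularity, path length, transitivity, and
    small-worldness normalized against degree-preserving null models),
    and classifies two-group cohorts with a class-weighted squared-slack
    linear support vector machine under leave-one-out cross-validation.
    Includes exhaustive feature-subset evaluation with exact sign tests,
    permutation-based group inference with false-discovery-rate control,
    regional degree-centrality comparisons, and a synthetic-cohort
    generator with plantable global and nodal group effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    kernlab,
    withr,
    optparse
Config/testthat/edition: 3
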