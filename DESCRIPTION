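Package: rsfcnet
Title: Resting-State Functional Connectivity Network Analysis and
    Group Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for group comparison of resting-state functional
    brain networks built from parcellated BOLD time series. Computes
    per-subject Pearson connectivity matrices, weighted network
    measures (node strength, eigenvector centrality, clustering
    coefficient), edge-wise general-linear-model statistics with
    Freedman-Lane permutation p-values and false-discovery-rate
    control, cluster-based permutation tests over anatomically
    ordered nodes, assembly of the significant "specific" subnetworks
    with BrainNet Viewer export, and pseudo-inverse linear
    discriminant classification with repeated stratified k-fold
    cross-validation. Includes a seeded synthetic-cohort generator
    with planted block-wise connectivity effects for benchmarking.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
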