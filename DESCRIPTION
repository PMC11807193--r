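Package: mnm
Title: Subpopulation-Aware Single-Cell Copy-Number and Replication Timing
    Analysis
Version: 1.0.0
Authors@R:
    person("Alex", "Moreau", email = "alex.moreau@posteo.net",
           role = c("aut", "cre"))
Description: Disentangles heterogeneous single-cell whole-genome sequencing
    samples from their DNA copy-number profiles alone. Provides
    distance-weighted k-nearest-neighbour imputation of missing copy
    numbers, an expectation-maximisation log-normal mixture filter for
    sequencing barcode validation, a small feed-forward neural network
    that classifies cells as replicating (S phase) or non-replicating,
    density-based discovery of genomic subpopulations in a UMAP embedding
    with matching of replicating cells to their subpopulation of origin,
    and downstream replication-timing utilities (pseudo-bulk profiles,
    Spearman correlation atlases, trajectory permutation tests). A
    synthetic-cohort simulator generates clonal populations, S-phase
    cells, missingness and barcode read counts so that every stage can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    uwot,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
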