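Package: karyotopics
Title: Expression-Based Karyotyping, Topic Modeling and Signature Scoring
    for Single-Cell Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for single-cell RNA-seq analyses of
    developing meninges and meningeal tumours: inference of integer
    chromosomal copy numbers from expression alone (per-cell ploidy
    tracks against a reference atlas, metacell grouping, and hidden
    Markov model segmentation), latent Dirichlet allocation topic
    modeling of UMI counts with transfer of fitted topics to spatial
    panels and bulk profiles, gene-signature scoring with
    expression-matched control genes, meningeal layer-maturation
    assignment, cell-cycle scoring, cluster enrichment, two-round
    quality-control filtering, and spatial transcript table processing.
    A synthetic-data module generates every required input with known
    ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    graphics,
    Rcpp,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
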