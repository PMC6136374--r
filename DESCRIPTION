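Package: abacross
Title: Crosstalk Analysis of ABA-Dependent and ABA-Independent Drought-Response Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classifies drought-responsive genes from multi-contrast RNA-seq
    summaries into ABA-dependent, ABA-independent and not-recovered classes,
    and tests whether the two pathway gene sets interact more than expected in
    a protein-protein interaction network. The null model is an ensemble of
    degree-preserving edge-shuffled networks; enrichment is quantified by
    per-gene empirical p-values, a global Z-score, a Z-score comparison
    against size-matched non-DEG gene sets, and co-expression link enrichment
    among the most correlated gene pairs. Includes a synthetic-data module
    (configuration-model networks with planted cross-set enrichment, contrast
    tables with known classes, latent-factor expression matrices) so the full
    pipeline is testable against known ground truth, plus Cytoscape-ready
    SIF/GraphML export of the core interacting subnetwork.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
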