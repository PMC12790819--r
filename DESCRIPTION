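Package: stplate
Title: Reference-Free Simulation of Spatial Transcriptomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates spatial transcriptomics data without requiring a real spatial
    reference. Cell coordinates are drawn on a rectangular plate, cell-type labels are
    assigned by constrained simulated annealing (global, local, or batched with
    hierarchically shrinking zones) so that neighbourhood transition frequencies and
    global type proportions match user targets, expression profiles are attached from a
    labelled single-cell reference or a built-in negative-binomial simulator, and
    single-cell data can be aggregated to spot-level data with exact ground-truth
    compositions. Includes an evaluation suite: adjusted Rand index, normalised mutual
    information, transition/centrality/neighbourhood-enrichment matrix discrepancies,
    Ripley's L curves with cosine similarity, and ligand-receptor set agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    deldir,
    igraph,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    spatstat.explore,
    spatstat.geom,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
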