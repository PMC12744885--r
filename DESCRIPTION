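Package: coexscreen
Title: Candidate-Gene Co-Expression Screening in Bulk and Single-Cell
    Transcriptomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens a panel of candidate genes for co-regulation with an
    anchor gene pair (e.g. the two Drosophila collagen IV subunit genes
    Col4a1 and viking) across bulk expression compendia and single-cell
    transcriptomes. Implements correlation ranking against a reference gene
    over multi-sample bulk panels, KNN metacell aggregation of sparse
    single-cell counts, per-cell-type weighted gene co-expression networks
    (soft-power selection by scale-free topology fit, topological overlap,
    average-linkage module detection, module eigengenes), and a Monte Carlo
    permutation test of candidate/anchor module co-assignment backed by an
    exact Poisson-binomial oracle. Ships synthetic-data generators with
    planted co-regulation so the full pipeline can be validated against a
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: GeneExpression, Network, SingleCell, Transcriptomics,
    NetworkInference, Software
RoxygenNote: 7.3.3
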