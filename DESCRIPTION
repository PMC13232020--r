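Package: TcellTrails
Title: Reconstruction of T Cell Migration Trails from Spatial Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs putative T cell migration trails on 10x Visium and
    Visium HD spatial transcriptomics slides by stitching adjacent
    T-cell-infiltrated spots along increasing exhaustion scores. Provides
    regression-residual exhaustion scoring, trail search by minimum-weight
    spanning paths (Dijkstra) and by proximity to a straight line in
    (x, y, score) space, coherence-based trail selection against alternative
    routes, matched-control permutation machinery, mixed-effects gradient
    tests, empirical differential expression, shared TCR/BCR variable-gene
    analysis, Fisher over-representation analysis, phenotype ranking against
    single-cell cluster means, and a synthetic slide generator with planted
    ground-truth trails.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
biocViews: Spatial, Transcriptomics, GeneExpression, Software
RoxygenNote: 7.3.3
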