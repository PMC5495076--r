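Package: cmint
Title: Chromatin Module Inference on Cell Lineage Trees
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Joint probabilistic clustering of multi-mark chromatin signal
    across related cell types. Each cell type is modelled as a mixture of k
    diagonal-covariance Gaussians (chromatin modules) and the mixtures are
    coupled along a rooted cell lineage tree by per-branch module transition
    matrices, so that a locus's module assignment in a child cell type depends
    on its assignment in the parent. Parameters are estimated by
    expectation-maximization with exact two-pass sum-product message passing
    on the tree. The package also provides MDL-penalized cross-validated
    selection of the module number, likelihood-based comparison of candidate
    lineage topologies, MERGE-FIRST and CLUSTER-FIRST baseline clusterings
    with Hungarian label matching, cluster-quality and transition-detection
    metrics, module-similarity matrices, rule-based transition queries,
    hypergeometric enrichment with Benjamini-Hochberg correction, and a
    simulator that draws datasets from the generative model with ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    cluster,
    ape,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Epigenetics, Clustering, HistoneModification, ChIPSeq,
    GeneRegulation
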