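Package: treenetmfa
Title: Integration of Trees and Networks via Multidimensional Scaling and
    Multiple Factor Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares and integrates heterogeneous object representations
    (ultrametric dendrograms, undirected networks, numeric tables) built on a
    shared entity set. Each object is projected to Euclidean coordinates by
    extracting a dissimilarity matrix (cophenetic distance for trees,
    shortest-path distance for networks) and applying classical
    (Torgerson) multidimensional scaling; the coordinate tables are then
    integrated with Multiple Factor Analysis. Group coordinates of the MFA
    drive a clustering of the objects, from which per-cluster consensus
    trees (hierarchical clustering of MFA individual coordinates) and
    strict-majority consensus networks are built. A kernel-combination
    baseline (double-centred kernels, Frobenius-cosine similarity,
    consensus kernels) and stochastic simulation benchmarks (grouped
    Gaussian tables, stochastic block models) are included, together with
    evaluation metrics (adjusted Rand index, pairwise edge confusion rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
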