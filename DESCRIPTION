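Package: embedaudit
Title: Distortion Audits for Low-Dimensional Embeddings of Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the distortion incurred when high-dimensional single-cell
    expression profiles are reduced to two dimensions. Provides neighbor-set
    Jaccard dissimilarity, cell-type ranking correlations, equidistant-group
    max/min distance-ratio inflation, label-mixing fractions, k-nearest-neighbor
    label prediction, inter-/intra-type distance separation, relative contrast of
    L1 versus L2 norms, and a Johnson-Lindenstrauss minimum-dimension bound. Also
    implements Picasso, a shape-constrained encoder that embeds any dataset into
    an arbitrary 2D silhouette (an elephant, a flower) while preserving ambient
    pairwise distances comparably to t-SNE or UMAP, plus a synthetic scRNA-seq
    count generator and geometric benchmarks (Swiss roll, hypercube, regular
    simplices) so every audit runs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    irlba,
    uwot,
    Rtsne,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    rhdf5,
    igraph,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
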