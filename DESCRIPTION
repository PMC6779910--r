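Package: imagemine
Title: Whole-Image Profiling and Mining via Feature-Vector Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scriptable image analytics for smaller biological image sets.
    Images are profiled as fixed-length feature vectors by a pluggable
    embedding backend (a registry of deep-network penultimate-layer
    embedders plus a built-in deterministic filter-bank profiler), then
    mined with small-scale machine learning: cosine/euclidean distance
    matrices, agglomerative hierarchical clustering with Ward and other
    linkages (dendrogram cutting, branch selection, Newick export),
    metric multidimensional scaling by stress majorization, and
    cross-validated logistic-regression phenotype classification with
    confusion-matrix cell drill-down. Includes generators for labelled
    synthetic microscopy-like image sets (ring-versus-dispersed nuclear
    texture; aggregate morphologies) so the whole pipeline is testable
    offline, and a command-line interface reproducing the unsupervised
    and supervised workflows end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    digest,
    glmnet,
    jsonlite,
    pROC,
    png,
    stats,
    tiff,
    jpeg,
    tools,
    utils,
    yaml,
    EBImage
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
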