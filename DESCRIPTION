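Package: scbridge
Title: Synthetic Multimodal Bridges for Diagonal Single-Cell Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates synthetic paired multi-omic single cells from unpaired (or
    paired) single-cell modality embeddings using a Wasserstein GAN with gradient
    penalty, trained on mini-batches matched across modalities by Laplacian-eigenmap
    ordering and Bayesian-ridge scoring. The synthetic cells act as bridges for
    label and feature transfer between modalities (kNN feature reconstruction and
    two-stage kNN label propagation). Includes the quantitative evaluation suite:
    adjusted mutual information, homogeneity/completeness/V-measure, the local
    inverse Simpson index (LISI), and a preranked-GSEA confusion-matrix cell-type
    accuracy, plus a simulator of multimodal studies with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    igraph,
    RSpectra,
    FNN,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
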