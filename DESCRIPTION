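Package: dreamgnn
Title: Dual-Route Graph Neural Networks for Drug-Disease Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts drug-disease associations by bipartite link prediction
    with a dual-route graph neural network: a relation-aware topology encoder
    (graph-convolutional matrix completion with basis-decomposed relation
    weights) over the drug-disease interaction graph, and a feature-aware
    similarity encoder (two-layer graph convolutions over predefined and
    embedding-derived k-nearest-neighbour similarity graphs), fused per node
    by learned additive attention and scored by a multilayer-perceptron
    decoder. Includes harmonisation of heterogeneous pretrained embeddings
    (masked mean pooling, zero padding, PCA), leakage-free 10-fold
    cross-validation with full negative evaluation, strict cold-start
    inference for unseen entities via temperature-scaled neighbour attention,
    and a planted-block synthetic data generator so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
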