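Package: kpnn
Title: Knowledge-Primed Neural Networks for Interpretable Deep Learning
    on Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds sparse feed-forward neural networks from prior-knowledge
    regulatory graphs (signaling interactions and transcription-factor/target
    relations), trains them on single-cell expression data with an
    interpretability-optimized procedure (hidden-node and input-node dropout,
    weighted cross-entropy with L2 regularization, checkpoint-based early
    stopping), and quantifies the importance of signaling proteins and
    transcription factors by perturbation-based node weights. Includes matched
    control networks (fully connected, edge-matched sparse, and
    degree-preserving shuffled networks), differential node-weight statistics
    against connectivity-normalizing control inputs, structural network
    comparison, and a ground-truth simulator of single-cell counts by binomial
    read subsampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    generics,
    igraph,
    limma,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    pROC,
    optparse
Config/testthat/edition: 3
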