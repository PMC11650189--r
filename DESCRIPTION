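Package: gradix
Title: Functional Connectome Gradients, Transcriptomic Association, and
    Treatment-Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construction of functional connectome gradients by diffusion map
    embedding of normalized-angle affinity matrices, with iterative Procrustes
    alignment across subjects; covariate-adjusted group inference on gradient
    maps with permutation cluster-extent correction; small-world network
    topology (aGamma, aLambda, aSigma) over a sparsity range; spin-permutation
    spatial nulls for map-to-map inference and meta-map decoding; partial least
    squares linking regional gene expression to case-control gradient maps with
    bootstrap gene-weight Z ranking; permutation overlap and preranked GSEA
    enrichment of gene lists; and leave-one-out support-vector-regression
    prediction of treatment outcomes from baseline gradients. A synthetic-data
    generator plants known gradient, transcriptomic, and outcome effects so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2), methods
Imports:
    stats,
    utils,
    tools,
    igraph,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
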