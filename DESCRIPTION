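Package: MLtiplet
Title: Multi-Omic Doublet and Multiplet Detection for Droplet Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies doublets and multiplets in droplet-based single-cell
    RNA-seq by first deriving ground-truth-like doublet labels from CITE-seq
    antibody co-positivity (mutually exclusive marker pairs, per-antibody
    linear-discriminant thresholds) and V(D)J receptor-chain co-capture
    (a rule engine over productive BCR/TCR contigs), then generalising those
    labels to all droplets with a logistic generalized linear model over
    droplet features: the mito-ribo ratio, per-sample centred log-ratio
    transformed UMI covariates, and cell-type module scores. Includes a
    Gaussian-mixture threshold for apoptotic droplets, a doublet-spiking
    simulation protocol, and a fully synthetic multi-omic data generator so
    the whole method can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    glmnet,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
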