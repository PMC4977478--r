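Package: enhancerDNN
Title: Enhancer Prediction from Histone-Modification Signatures with an
    Interpretable Deep Feedforward Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts distal enhancer elements from ChIP-seq histone-modification
    enrichment using a small fully connected feedforward neural network with
    softplus activations and dropout, trained on p300-anchored positive sites and
    TSS/background negatives. Reads are binned into fixed-width genomic bins,
    RPKM-normalized, and windowed around candidate sites to form the feature
    matrix. Model interpretability is provided by backward propagation of
    absolute connection weights, yielding per-feature and per-histone-mark
    importance scores that drive a top-k feature-reduction loop. Evaluation uses
    a validation-rate protocol against true-positive markers (distal DHS, p300,
    CBP, TFBS) with threshold sweeps and class-distribution overlap statistics.
    A synthetic-epigenome generator with planted, parameterized enhancer and
    promoter signatures makes the entire pipeline runnable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    graphics,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
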