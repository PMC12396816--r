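Package: thriftySHM
Title: Parameter-Efficient Wide-Context Models of Somatic Hypermutation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Context-dependent models of the somatic hypermutation (SHM)
    process that diversifies B-cell receptor sequences. Implements
    parameter-efficient ("thrifty") convolutional models over trainable
    3-mer embeddings that predict per-site mutation rates and conditional
    substitution probabilities, a 5-mer table baseline, a censored
    exponential waiting-time likelihood with branch-length offsets,
    training and branch-length optimization machinery, imbalance-aware
    evaluation metrics (AUROC, AUPRC, R-precision, substitution accuracy,
    binned observed/expected overlap), fourfold-degenerate synonymous-site
    masking, parent-child pair extraction from clonal-family trees, and a
    seeded simulator of context-dependent mutation for calibration and
    parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
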