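Package: regulonbench
Title: Signed Transcription Factor Regulons from Literature Evidence with
    Perturbation Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds signed, weighted transcription factor (TF) regulons by
    aggregating multi-resource literature evidence (PubMed-identifier
    deduplication, complex-member merging, regulator-class filtering) and
    assigning each TF-gene edge a mode of regulation through a decision
    cascade (PMID prevalence, regulon majority, TF-level prior knowledge,
    default activating). Scores TF activities from gene-level expression
    signatures with a univariate linear model and evaluates regulon
    collections against TF-perturbation signature compendia using
    class-balanced downsampled AUROC/AUPRC with a degree-preserving permuted
    network baseline and size-bias diagnostics. Includes a synthetic-data
    generator for ground-truth networks, noisy evidence tables and knockdown
    signature compendia so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
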