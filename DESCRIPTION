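Package: fopa
Title: Pathway Analysis by Probabilistic Model Checking of Signaling Topologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies perturbed signaling pathways from two-class gene
    expression experiments by compiling each pathway topology into a
    probabilistic guarded-command model over a six-state per-gene encoding,
    computing the probability that final-effector genes become differentially
    activated (reachability of state 4 in the induced discrete-time Markov
    chain), and assessing pathway scores against a sample-label permutation
    null. Includes a KGML (KEGG XML) reader, an explicit-state and a
    Monte-Carlo reachability engine, moderated-t gene statistics with
    empirical-Bayes variance shrinkage, and a synthetic benchmark suite
    (decoy pathways, label permutation, topology perturbation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    xml2,
    S4Vectors,
    SummarizedExperiment,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
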