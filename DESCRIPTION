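Package: kinemod
Title: DNA Modification Detection from SMRT Sequencing Polymerase Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects DNA base modifications (N6-methyladenine, N4-methylcytosine
    and related marks) from single-molecule real-time sequencing polymerase
    kinetics. Raw inter-pulse durations (IPDs) are Box-Cox transformed toward
    normality and centered per movie to remove batch effects; positions sharing
    a local sequence context ("homologous positions") are pooled through an
    empirical-Bayes hierarchical model with a conjugate normal-inverse-chi-square
    prior, fitted by EM; each genomic position and strand is scored with a
    marginal log-likelihood ratio, with or without a whole-genome-amplified
    control sample. Includes sequence-context effect estimation by gradient
    boosted regression trees, a synthetic kinetics simulator, and an evaluation
    suite (positional-tolerance matching, subsampled ROC, motif-based
    conservative FDR).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    xgboost,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    pROC,
    optparse
Config/testthat/edition: 3
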