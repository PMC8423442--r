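Package: dmcnet
Title: Single-Unit Statistics, Population Decoding, and Two-Module
    Recurrent Network Models for Delayed Match-to-Category Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying sequential match/nonmatch category
    decisions in frontoparietal circuits. Provides a synthetic
    delayed match-to-category (DMC) task and spike/LFP generator with
    known ground-truth tuning; single-unit selectivity statistics
    (unbiased fraction of explained variance, sliding-window ROC, an
    ROC-based category tuning index, selectivity latency, firing-rate
    decimation, error-trial ROC); pseudo-population linear-SVM
    decoding including cross-sample-condition generalization; a
    nonlinearity index and neuron classification for mixed
    sample-by-test category coding; and trainable two-module
    excitatory/inhibitory recurrent networks obeying Dale's law, with
    in-silico graded inactivation and projection-ablation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
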