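Package: rtepi
Title: Predicting Enhancer-Promoter Interactions from DNA Replication Timing
Version: 0.1.0
Authors@R:
    person("rtepi", "developers", email = "rtepi@example.org", role = c("aut", "cre"))
Description: Builds labelled enhancer-promoter interaction (EPI) datasets from
    chromatin loops (Hi-C, ChIA-PET, Hi-TrAC, 5C style BEDPE) and element
    annotations, encodes each candidate pair as a multi-scale replication-timing
    (RT) feature vector (482 dimensions by default), and trains an interpretable
    random-forest classifier that predicts EPIs from RT profiles alone.
    Includes distance-matched negative sampling, cross-validation and resampling
    evaluation with native AUPRC/AUROC, feature-importance and incremental
    feature selection, cross-platform loop recovery and model combination, a
    two-group (cancer vs normal) sample-level EPI calling pipeline with
    clustering quality metrics, and a fully seeded synthetic RT/loop generator
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    GenomeInfoDb,
    knitr,
    rmarkdown
Config/testthat/edition: 3
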