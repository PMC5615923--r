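Package: foxomics
Title: Tissue-Specific Proteomic Dissection of FoxO-Dependent Insulin Signalling Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for classifying tissue-specific proteomic
    responses to reduced insulin/IGF-like signalling (IIS) as FoxO-dependent or
    FoxO-independent. Implements Perseus-style missing-value filtering and
    down-shifted normal imputation for label-free quantification (LFQ)
    intensities, empirical-Bayes moderated linear models over a four-genotype
    design with interaction contrasts, confidence-interval equivalence testing
    against a data-derived margin, degree-normalized network propagation with
    topology-bias correction and hierarchical clustering of smoothed profiles,
    elim-Fisher ontology enrichment, position-weight-matrix promoter scanning
    with exact score p-values, and a synthetic-data generator with planted
    ground truth so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    Biostrings,
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
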