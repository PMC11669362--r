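Package: immunomark
Title: Pathway Activation Scoring and Biomarker Signatures for Immune
    Checkpoint Inhibitor Response
Version: 0.1.0
Authors@R:
    person("Oncobox", "Analytics", email = "devnull@example.org",
           role = c("aut", "cre"))
Description: A pipeline for screening molecular biomarkers of response to
    immune checkpoint inhibitor (ICI) therapy from bulk tumor RNA-seq and
    exome-derived features. Implements median-of-ratios normalization with
    a pseudo-count, case-to-normal expression ratios against a control
    panel, pathway activation level (PAL) scoring with activator/repressor
    roles, gene-centric pathway construction from a merged interactome,
    biomarker screening against RECIST response (ROC AUC, Mann-Whitney,
    Fisher) and progression-free survival (threshold-optimized Cox
    stratification with a minimum group-size constraint), and construction
    of a multi-component risk-score signature by backward elimination over
    a ridge-penalized logistic model. A seed-reproducible synthetic cohort
    generator with planted effects supports end-to-end testing without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    igraph,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
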