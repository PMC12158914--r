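Package: hccbn
Title: Bayesian-Network Counterfactual Analysis of Hepatocellular
    Carcinoma Treatment Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for auditing hepatocellular carcinoma (HCC) treatment
    decisions against the Barcelona Clinic Liver Cancer (BCLC) management
    flowchart and for estimating individualised treatment effects with
    discrete Bayesian networks.  Provides exact inference by variable
    elimination, conditional-probability-table learning with a Dirichlet
    smoothing prior, graph surgery for interventions (the do-operator), and
    the abduction-action-prediction algorithm for case-level counterfactual
    survival queries.  Includes cohort cleaning and posterior-mode
    imputation of treatment waiting times, a declarative BCLC rule engine
    for guideline-compliance classification, and a synthetic-cohort
    generator with ground-truth potential outcomes for end-to-end recovery
    experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    pROC,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
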