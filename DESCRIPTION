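Package: netsegfc
Title: Functional Network Segregation and Brain-Behaviour Association
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how functional brain network organization
    relates to behaviour in ageing cohorts. Builds subject-level functional
    connectivity matrices from region-of-interest (ROI) time series
    (Pearson correlation with Fisher r-to-z transformation), computes
    global and network-level system segregation together with intra- and
    inter-network mean connectivity, scores handgrip strength and
    cognitive T-score composites, runs covariate-adjusted linear-model
    association families with Benjamini-Hochberg false discovery rate
    correction, and performs residualized single-mediator analysis with
    percentile-bootstrap confidence intervals. Includes a block-covariance
    synthetic cohort generator so that the entire pipeline can be exercised
    and validated without access to restricted participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'connectivity.R'
    'partition.R'
    'segregation.R'
    'phenotypes.R'
    'association.R'
    'mediation.R'
    'synthetic.R'
    'pipeline.R'
    'io.R'
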