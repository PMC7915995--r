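Package: danprisk
Title: DEMATEL-DANP Influence Analysis and Additive Risk Scoring for
    Clinical Decision Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Turns expert pairwise-influence questionnaires into a weighted
    clinical risk-assessment model. Implements the DEMATEL technique
    (panel aggregation with a running-mean consensus check, matrix
    normalization, the total-influence matrix T = N(I - N)^-1,
    prominence/net-relation analytics and influence-network edge
    extraction), the DEMATEL-based ANP (DANP) limit-supermatrix
    derivation of per-criterion influential weights, simple additive
    weighting (SAW) of patient grades, experience-weighted group
    re-aggregation of expert panels, and a synthetic expert-panel
    generator for testing the whole pipeline without raw survey data.
    Ships a worked acute-kidney-injury (AKI) risk model for elderly
    patients as the packaged example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
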