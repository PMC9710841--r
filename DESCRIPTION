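Package: egostates
Title: Workplace Social Network Structure and Personality State Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline linking passively sensed workplace interaction logs to
    week-level variability in Big Five personality states. Builds undirected
    weighted weekly contact networks from directed badge detection logs using a
    reciprocity-reconciliation (minimum count) rule, computes 26 global and
    egocentric social network features (including Burt effective size,
    constraint and efficiency), derives root-mean-square-of-successive-
    differences (RMSSD) outcomes from thrice-daily momentary self-reports, and
    fits leave-one-subject-out gradient-boosted tree models with permutation
    feature importance scaled 0-100 and aggregated across traits. A synthetic
    cohort generator with planted volatility drivers makes the full pipeline
    testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    xgboost,
    glmnet,
    caret,
    stats,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
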