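Package: cytocsf
Title: Simulation, Hierarchical Gating and Diagnostic Scoring of Pediatric CSF
    Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing cerebrospinal-fluid (CSF) immune-cell flow
    cytometry in pediatric neurological disorders. Provides a seeded synthetic
    cohort generator for per-donor event-level cytometry data across seven
    diagnosis groups (non-inflammatory and inflammatory controls, MS, MOGAD and
    other acquired demyelinating syndromes), a declarative hierarchical gating
    engine with fixed or mixture-derived thresholds, population frequency and
    absolute-count (cells/mL) summaries, the ASC-to-CD14+ myeloid ratio (AMR)
    and neuroinflammatory composite scores (coNCS and full NCS) with their zero
    rules, nonparametric cross-group statistics, and ROC/AUC evaluation of the
    score-based classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mclust,
    pROC,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
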