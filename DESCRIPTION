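Package: mpascore
Title: MAPK Pathway Activity Scoring and Biomarker Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes aggregated transcriptional pathway-activity scores
    (the 10-gene MAPK pathway activity score and a housekeeping-gene
    negative-control score) from panel or RNA-seq expression matrices,
    evaluates them as predictors of drug sensitivity against an
    elastic-net expression model and mutation status, fits four-parameter
    logistic dose-response curves, and assesses prognostic value with Cox
    proportional-hazards models, Kaplan-Meier threshold scans and
    sliding-percentile-window hazard scans. A seeded synthetic-cohort
    generator reproduces the statistical structure the analyses assume
    (latent pathway activity driving signature-gene expression, drug
    sensitivity and survival hazard), so every pipeline stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    survival,
    glmnet,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
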