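Package: grstrata
Title: Obesity-Stratified Genetic Association Analysis and
    Obesity-Specific Genetic Risk Scores for Type 2 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing gene-obesity interaction on type 2
    diabetes (T2D) in epidemiological cohorts: genotype coding and
    Hardy-Weinberg checks, stratified logistic and Cox regression with
    formal interaction tests, person-time incidence analysis,
    Kaplan-Meier curves, classification-style predictive values,
    construction and evaluation of obesity-specific genetic risk
    scores (unweighted risk-allele counts partitioned by the obesity
    stratum in which each SNP is more strongly associated with T2D),
    repeated-measures modelling of BMI trajectories, and a synthetic
    cohort generator with Monte-Carlo power estimation so that every
    stage of the pipeline can be exercised without access to
    individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
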