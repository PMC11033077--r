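Package: equicomorb
Title: Equivalence Testing for Genetically Unrelated Comorbidities in EHR Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies phenotypes that are significantly comorbid with an
    index disorder in electronic health record (EHR) data yet show
    statistically significant absence of polygenic-risk-score (PRS)
    association. Implements phecode-based case/control/missing status
    assignment with exclusion-range handling, phenome-wide pairwise logistic
    comorbidity regressions per site, shared-patient-weighted cross-site
    Z-score combination with Bonferroni control, PRS phenome-wide association
    with fixed-effect inverse-variance-weighted meta-analysis, two one-sided
    tests (TOST) of equivalence on Cohen's d bounds with Fisher's-method
    cross-site combination, and a tier classification separating
    consequence-driven from genetically loaded comorbidities. A two-site
    synthetic cohort generator with known ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
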