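Package: brainAGE
Title: Brain-Age Gap Estimation and Combined Lifestyle Risk Modelling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying lifestyle-associated acceleration of
    structural brain aging. Implements derivation of lifestyle exposures
    (pack-years of smoking, pure alcohol in grams per month, a Berkman-style
    social integration index, and MET-hour physical activity), a combined
    lifestyle risk score built from shifted sign-aligned z-scores,
    machine-learning brain-age estimation from gray-matter probability
    features via principal component reduction and sparse Bayesian relevance
    vector regression with sex-split leave-k-out cross-validation, quadratic
    age-bias detrending of the resulting brain-age gap (BrainAGE), and the
    downstream statistical layer: multiple regression under three
    age-handling approaches, effect quantification in months, sex
    interaction and stratified analyses, quadratic curve comparison,
    age-matched smoker-group contrasts, and noncentral-F power analysis.
    A calibrated synthetic cohort generator with known ground-truth effects
    makes the full pipeline testable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
biocViews: StatisticalMethod, Regression, Classification, Aging
Config/testthat/edition: 3
RoxygenNote: 7.3.3
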