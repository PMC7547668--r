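Package: mmtraj
Title: Multimorbidity Trajectories via Hidden Markov Models on Electronic Health Record Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Longitudinal analysis of multimorbidity patterns in elderly
    primary-care cohorts. Generates synthetic person-year panels with known
    ground truth, reduces mixed continuous/categorical features by principal
    component analysis and multiple correspondence analysis, seeds clusters
    with fuzzy C-means, fits a hidden Markov model with absorbing death and
    dropout states by Baum-Welch over many short sequences, decodes
    individual trajectories by Viterbi, characterizes the resulting patterns
    by observed/expected ratios and exclusivity, and estimates
    pattern-specific mortality hazards with Cox regression, chained-equation
    imputation of missing socio-economic status, and Rubin pooling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    survival,
    jsonlite,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
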