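Package: hypoxem
Title: EM Estimation of Exposure-Outcome Associations with a Missing Binary Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood estimation of the association between a rare
    binary outcome and a binary exposure that is unobserved in a large fraction
    of subjects, via an expectation-maximization (EM) algorithm that models the
    exposure from categorical covariates and fractionally weights the two
    possible exposure values of each untested subject.  Supports both
    missing-at-random analysis and a parameterized not-missing-at-random
    mechanism in which untested subjects carry a user-specified ratio r of the
    covariate-conditional exposure probability of tested subjects, with
    sensitivity sweeps over a grid of r values.  Includes a pH-threshold
    classifier for perinatal hypoxia, descriptive ascertainment and outcome-rate
    tables, a synthetic perinatal cohort simulator with controllable missingness
    mechanisms, and parameter-recovery experiment harnesses.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
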