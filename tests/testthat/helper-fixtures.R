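# Fixtures are built in code: a hand-sized cohort for I/O and tallying tests,
# and a compact simulation configuration (2 exposure covariates, 1 confounder)
# used wherever the full 8-covariate default would only slow the test down.

toy_schema <- function() {
  cohort_schema(
    maternal_age = c("<=25", "25-30", "30-35", ">35"),
    parity = c("0", "1", "2", "3", "4+"),
    smoking = c("0", "1")
  )
}

# 6 records with known pH panels, exposures, and covariates
toy_cohort <- function() {
  tab <- tibble::tibble(
    id = paste0("C", 1:6),
    gender = factor(c("male", "male", "female", "female", "male", "female"),
                    levels = c("male", "female")),
    asd = c(1L, 0L, 0L, 1L, 0L, 0L),
    scalp_ph = c(7.10, NA, NA, NA, 7.30, NA),
    arterial_ph = c(7.30, 7.19, NA, 7.20, NA, NA),
    venous_ph = c(NA, NA, 7.40, NA, NA, NA),
    fullterm = c(1L, 1L, 0L, NA, 1L, 1L),
    maternal_age = factor(c("<=25", "25-30", ">35", "30-35", "<=25", "25-30"),
                          levels = c("<=25", "25-30", "30-35", ">35")),
    parity = factor(c("0", "1", "2", "0", "4+", "3"),
                    levels = c("0", "1", "2", "3", "4+")),
    smoking = factor(c("0", "1", "0", "0", "1", "0"), levels = c("0", "1"))
  )
  tab$hypoxia <- classify_hypoxia(tab$scalp_ph, tab$arterial_ph, tab$venous_ph)
  attr(tab, "schema") <- toy_schema()
  tab
}

compact_covariates <- function() {
  list(
    covariate_spec("smoking", c("0", "1"), c(0.80, 0.20)),
    covariate_spec("parity", c("0", "1", "2+"), c(0.45, 0.35, 0.20))
  )
}

compact_confounders <- function() {
  list(covariate_spec("ses", c("low", "mid", "high"), c(0.25, 0.50, 0.25)))
}

# Compact generator: exposure prevalence ~0.14, controllable outcome rate.
# outcome_intercept -6.2 gives the rare (~0.5%) outcome of the emulated
# setting; -1.5 gives a common outcome for small-n optimizer comparisons.
quick_sim_config <- function(n, missingness = missingness_spec("mcar", rate = 0.5),
                             outcome_intercept = -6.2,
                             exposure_log_or = log(1.5),
                             male_log_or = log(5), seed = 1L) {
  gamma <- c("(Intercept)" = -1.85, "smoking=1" = 0.5,
             "parity=1" = -0.3, "parity=2+" = -0.5)
  beta <- c("(Intercept)" = outcome_intercept, exposure = exposure_log_or,
            "ses=mid" = -0.1, "ses=high" = -0.2, "gender=male" = male_log_or)
  simulation_config(n, compact_covariates(), compact_confounders(),
                    gamma, beta, missingness, seed = seed)
}

quick_spec <- function() {
  model_spec(c("exposure", "ses", "gender"), c("smoking", "parity"))
}

# small-instance generator for optimizer-oracle comparisons: common outcome,
# mild effects, no separation risk
small_instance <- function(n = 300, seed = 1,
                           missingness = missingness_spec("mcar", rate = 0.4)) {
  cfg <- quick_sim_config(n, missingness = missingness,
                          outcome_intercept = -1.5,
                          exposure_log_or = log(2), male_log_or = 0.5,
                          seed = seed)
  simulate_cohort(cfg)
}

expect_schema_equal <- function(a, b) {
  expect_identical(unclass(attr(a, "schema")), unclass(attr(b, "schema")))
}
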