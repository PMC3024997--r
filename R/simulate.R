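# Synthetic perinatal cohorts with the statistical structure the estimator
# assumes: categorical maternal/obstetric covariates Z drive a binary exposure
# X, a rare binary outcome Y is driven by X, gender and confounders W, and X
# is masked by an MCAR, MAR, or NMAR mechanism with a controllable sensitivity
# ratio r.  Truth columns are retained so every stage is testable.

#' Specify a categorical covariate for simulation
#'
#' @param name Covariate name.
#' @param categories Ordered category labels (first = reference).
#' @param probabilities Marginal category probabilities (must sum to 1).
#' @return A list of class `covariate_spec`.
#' @export
covariate_spec <- function(name, categories, probabilities) {
  if (length(categories) != length(probabilities)) {
    stop("categories and probabilities must have equal length", call. = FALSE)
  }
  if (abs(sum(probabilities) - 1) > 1e-12 || any(probabilities < 0)) {
    stop(sprintf("probabilities of '%s' must be a simplex", name), call. = FALSE)
  }
  structure(list(name = name, categories = as.character(categories),
                 probabilities = probabilities),
            class = "covariate_spec")
}

#' Specify the exposure-missingness mechanism
#'
#' @param mechanism `"mcar"` (uniform), `"mar"` (logistic in observed drivers)
#'   or `"nmar"` (depends on the unobserved exposure itself, calibrated to a
#'   target sensitivity ratio `r`).
#' @param rate Target overall missing fraction in (0, 1).
#' @param r Target sensitivity ratio in (0, 1\]; required iff `mechanism =
#'   "nmar"`.
#' @param mar_terms Covariate names (optionally including `"asd"`, the
#'   outcome) driving MAR missingness; required iff `mechanism = "mar"`.
#' @return A list of class `missingness_spec`.
#' @export
missingness_spec <- function(mechanism = c("mcar", "mar", "nmar"), rate = 0.5,
                             r = NULL, mar_terms = NULL) {
  mechanism <- match.arg(mechanism)
  if (rate <= 0 || rate >= 1) stop("rate must lie in (0, 1)", call. = FALSE)
  if (mechanism == "nmar") {
    if (is.null(r) || r <= 0 || r > 1) {
      stop("nmar requires a target r in (0, 1]", call. = FALSE)
    }
  } else if (!is.null(r)) {
    stop("target r is only meaningful for the nmar mechanism", call. = FALSE)
  }
  if (mechanism == "mar" && is.null(mar_terms)) {
    stop("mar requires mar_terms", call. = FALSE)
  }
  structure(list(mechanism = mechanism, rate = rate, r = r,
                 mar_terms = mar_terms),
            class = "missingness_spec")
}

design_names <- function(specs) {
  unlist(lapply(specs, function(s) paste0(s$name, "=", s$categories[-1])),
         use.names = FALSE)
}

#' Assemble a simulation configuration
#'
#' Coefficient vectors must be named and aligned to the encoded designs:
#' `gamma` to `c("(Intercept)", "<z>=<cat>", ...)` over `covariates`, `beta`
#' to `c("(Intercept)", "exposure", "<w>=<cat>", ..., "gender=male")` over
#' `confounders`, optionally plus `"gender=male:exposure"`.
#'
#' @param n Cohort size.
#' @param covariates List of [covariate_spec()] for the exposure drivers Z.
#' @param confounders List of [covariate_spec()] for the outcome confounders W.
#' @param gamma Named exposure-model coefficients (true values).
#' @param beta Named outcome-model coefficients (true values).
#' @param missingness A [missingness_spec()].
#' @param p_male Probability of male gender.
#' @param p_fullterm Probability of a full-term birth (independent flag kept
#'   for subset operations; gestation is not otherwise modelled).
#' @param seed Base seed; all randomness in [simulate_cohort()] flows from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n, covariates, confounders, gamma, beta,
                              missingness, p_male = 0.512, p_fullterm = 0.916,
                              seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  gamma_names <- c("(Intercept)", design_names(covariates))
  beta_names <- c("(Intercept)", "exposure", design_names(confounders), "gender=male")
  if (!setequal(names(gamma), gamma_names)) {
    stop(sprintf("gamma must be named exactly: %s", paste(gamma_names, collapse = ", ")),
         call. = FALSE)
  }
  if (!all(beta_names %in% names(beta)) ||
      !all(names(beta) %in% c(beta_names, "gender=male:exposure"))) {
    stop(sprintf("beta must be named exactly: %s (optionally plus gender=male:exposure)",
                 paste(beta_names, collapse = ", ")), call. = FALSE)
  }
  structure(list(n = as.integer(n), covariates = covariates,
                 confounders = confounders,
                 gamma = gamma[gamma_names],
                 beta = beta[intersect(c(beta_names, "gender=male:exposure"), names(beta))],
                 missingness = missingness, p_male = p_male,
                 p_fullterm = p_fullterm, seed = as.integer(seed)),
            class = "simulation_config")
}

# Exact expectation of logistic(intercept + offset) over the joint category
# distribution (covariates are independent, so the joint is enumerable), used
# to calibrate intercepts to target marginal rates deterministically.
calibrate_intercept <- function(offsets, probs, target) {
  stats::uniroot(function(c0) sum(probs * logistic(c0 + offsets)) - target,
                 lower = -25, upper = 10, tol = 1e-12)$root
}

enumerate_offsets <- function(specs, effects) {
  grids <- lapply(specs, function(s) seq_along(s$categories))
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  prob <- rep(1, nrow(combos))
  offset <- rep(0, nrow(combos))
  for (j in seq_along(specs)) {
    s <- specs[[j]]
    idx <- combos[[j]]
    prob <- prob * s$probabilities[idx]
    eff <- c(0, effects[paste0(s$name, "=", s$categories[-1])])
    offset <- offset + eff[idx]
  }
  list(offset = offset, prob = prob)
}

#' Default simulation configuration
#'
#' A scale-down of a provincial perinatal registry: eight categorical
#' maternal/obstetric covariates drive the exposure, birth-year and
#' socio-economic class confound the outcome, exposure prevalence among
#' tested subjects is ~14%, the outcome is rare (~0.5% overall) with a ~5:1
#' male:female ratio, and about half of exposures are missing.  Intercepts
#' are calibrated by exact enumeration of the category joint so the marginal
#' targets hold by construction.
#'
#' @param n Cohort size.
#' @param exposure_prevalence Target marginal exposure prevalence.
#' @param outcome_rate Target marginal outcome prevalence.
#' @param exposure_log_or True exposure log odds ratio in the outcome model.
#' @param male_log_or True male-gender log odds ratio.
#' @param interaction_log_or Optional true gender-by-exposure log odds ratio;
#'   `NULL` omits the product term.
#' @param missingness A [missingness_spec()]; default MAR at the missing
#'   fraction seen in perinatal testing practice (~52%), driven by
#'   pre-eclampsia, labor type and the outcome.
#' @param seed Base seed.
#' @return A `simulation_config`.
#' @export
default_sim_config <- function(n = 20000, exposure_prevalence = 0.14,
                               outcome_rate = 0.0052,
                               exposure_log_or = log(1.5),
                               male_log_or = log(5),
                               interaction_log_or = NULL,
                               missingness = missingness_spec(
                                 "mar", rate = 0.517,
                                 mar_terms = c("preeclampsia", "labor_type", "asd")),
                               seed = 1L) {
  covariates <- list(
    covariate_spec("maternal_age", c("<=25", "25-30", "30-35", ">35"),
                   c(0.22, 0.33, 0.28, 0.17)),
    covariate_spec("parity", c("0", "1", "2", "3", "4+"),
                   c(0.42, 0.33, 0.15, 0.06, 0.04)),
    covariate_spec("smoking", c("0", "1"), c(0.82, 0.18)),
    covariate_spec("diabetes", c("0", "1"), c(0.95, 0.05)),
    covariate_spec("preeclampsia", c("0", "1"), c(0.97, 0.03)),
    covariate_spec("labor_type", c("spontaneous", "induced", "none"),
                   c(0.60, 0.25, 0.15)),
    covariate_spec("presentation", c("cephalic", "breech"), c(0.96, 0.04)),
    covariate_spec("birthweight_class", c("2.5-4.5", "<2.5", ">4.5"),
                   c(0.90, 0.06, 0.04))
  )
  gamma_effects <- c(
    "maternal_age=25-30" = -0.05, "maternal_age=30-35" = 0.05,
    "maternal_age=>35" = 0.15,
    "parity=1" = -0.30, "parity=2" = -0.40, "parity=3" = -0.45,
    "parity=4+" = -0.50,
    "smoking=1" = 0.20, "diabetes=1" = 0.30, "preeclampsia=1" = 0.60,
    "labor_type=induced" = 0.35, "labor_type=none" = -0.40,
    "presentation=breech" = 0.40,
    "birthweight_class=<2.5" = 0.50, "birthweight_class=>4.5" = 0.20
  )
  enum_z <- enumerate_offsets(covariates, gamma_effects)
  gamma0 <- calibrate_intercept(enum_z$offset, enum_z$prob, exposure_prevalence)
  gamma <- c("(Intercept)" = gamma0, gamma_effects)

  confounders <- list(
    covariate_spec("birth_year", as.character(1998:2004), rep(1 / 7, 7)),
    covariate_spec("ses", c("low", "mid", "high"), c(0.25, 0.50, 0.25))
  )
  beta_effects <- c(
    stats::setNames(0.02 * (1:6), paste0("birth_year=", 1999:2004)),
    "ses=mid" = -0.10, "ses=high" = -0.20
  )
  p_male <- 0.512
  enum_w <- enumerate_offsets(confounders, beta_effects)
  # fold gender, exposure (and the optional product) into the enumeration;
  # X is independent of W and gender by construction
  mix <- expand.grid(w = seq_along(enum_w$offset), male = c(0, 1), x = c(0, 1))
  off <- enum_w$offset[mix$w] + male_log_or * mix$male + exposure_log_or * mix$x +
    (interaction_log_or %||% 0) * mix$male * mix$x
  pr <- enum_w$prob[mix$w] *
    ifelse(mix$male == 1, p_male, 1 - p_male) *
    ifelse(mix$x == 1, exposure_prevalence, 1 - exposure_prevalence)
  beta0 <- calibrate_intercept(off, pr, outcome_rate)
  beta <- c("(Intercept)" = beta0, exposure = exposure_log_or, beta_effects,
            "gender=male" = male_log_or)
  if (!is.null(interaction_log_or)) {
    beta <- c(beta, "gender=male:exposure" = interaction_log_or)
  }
  simulation_config(n, covariates, confounders, gamma, beta, missingness,
                    p_male = p_male, seed = seed)
}

#' Simulate a cohort with known truth
#'
#' Draws covariates independently per their category probabilities, the
#' exposure from `logistic(gamma . Z)`, the outcome from
#' `logistic(beta . (X, W, gender))`, and then masks the exposure by the
#' configured mechanism.  The true exposure (`truth_x`) and the missingness
#' indicator are kept as trailing columns.  Deterministic given the seed.
#'
#' @param config A [simulation_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A cohort tibble with attached schema (covariates and confounders)
#'   and the config stored as attribute `"sim_config"`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  n <- config$n
  draw <- function(s) {
    factor(sample(s$categories, n, replace = TRUE, prob = s$probabilities),
           levels = s$categories)
  }
  tab <- tibble::tibble(id = sprintf("S%07d", seq_len(n)))
  tab$gender <- factor(ifelse(stats::runif(n) < config$p_male, "male", "female"),
                       levels = c("male", "female"))
  for (s in config$covariates) tab[[s$name]] <- draw(s)
  for (s in config$confounders) tab[[s$name]] <- draw(s)
  tab$fullterm <- as.integer(stats::runif(n) < config$p_fullterm)

  schema <- do.call(cohort_schema, c(
    stats::setNames(lapply(config$covariates, `[[`, "categories"),
                    vapply(config$covariates, `[[`, "", "name")),
    stats::setNames(lapply(config$confounders, `[[`, "categories"),
                    vapply(config$confounders, `[[`, "", "name"))
  ))
  attr(tab, "schema") <- schema

  z_terms <- vapply(config$covariates, `[[`, "", "name")
  w_terms <- vapply(config$confounders, `[[`, "", "name")
  Xz <- build_outcome_design(tab, seq_len(n), z_terms, schema, 0)
  Xz <- Xz[, names(config$gamma), drop = FALSE]
  pi_z <- logistic(drop(Xz %*% config$gamma))
  x <- as.integer(stats::runif(n) < pi_z)

  out_terms <- c("exposure", w_terms, "gender")
  if ("gender=male:exposure" %in% names(config$beta)) {
    out_terms <- c(out_terms, "gender:exposure")
  }
  Xy <- build_outcome_design(tab, seq_len(n), out_terms, schema, x = x)
  Xy <- Xy[, names(config$beta), drop = FALSE]
  mu <- logistic(drop(Xy %*% config$beta))
  y <- as.integer(stats::runif(n) < mu)

  miss <- draw_missingness(config$missingness, tab, x, y, pi_z)

  tab$asd <- y
  tab$hypoxia <- factor(ifelse(miss == 1, "unknown",
                               ifelse(x == 1, "positive", "negative")),
                        levels = EXPOSURE_LEVELS)
  tab$truth_x <- x
  tab$missing_indicator <- miss
  cols <- c("id", "gender", "asd", "hypoxia", "fullterm", z_terms, w_terms,
            "truth_x", "missing_indicator")
  tab <- tab[cols]
  attr(tab, "schema") <- schema
  attr(tab, "sim_config") <- config
  tab
}

draw_missingness <- function(ms, tab, x, y, pi_z) {
  n <- length(x)
  if (ms$mechanism == "mcar") {
    return(as.integer(stats::runif(n) < ms$rate))
  }
  if (ms$mechanism == "mar") {
    lp <- rep(0, n)
    for (term in ms$mar_terms) {
      if (term == "asd") {
        lp <- lp + log(2) * y
      } else {
        cats <- levels(tab[[term]])
        lp <- lp + c(0, rep(log(1.5), length(cats) - 1))[as.integer(tab[[term]])]
      }
    }
    c0 <- stats::uniroot(function(c0) mean(logistic(c0 + lp)) - ms$rate,
                         lower = -25, upper = 25, tol = 1e-12)$root
    return(as.integer(stats::runif(n) < logistic(c0 + lp)))
  }
  # NMAR: per-subject miss probabilities (a_i, b) with a_i solved from the
  # target probability-ratio r, and b calibrated to the overall rate.
  rate_at <- function(b) {
    a <- solve_missingness_rates(pi_z, b, ms$r)$a
    mean(a * pi_z + b * (1 - pi_z)) - ms$rate
  }
  b <- stats::uniroot(rate_at, lower = 1e-6, upper = 1 - 1e-6, tol = 1e-10)$root
  a <- solve_missingness_rates(pi_z, b, ms$r)$a
  p_miss <- ifelse(x == 1, a, b)
  as.integer(stats::runif(n) < p_miss)
}

#' Solve NMAR missingness rates for a target sensitivity ratio
#'
#' Given the exposure probability `pi`, the missingness probability `b` for
#' unexposed subjects, and a target ratio `r` of exposure prevalence in the
#' missing versus the non-missing group, solves (by bisection to 1e-10) for
#' the missingness probability `a` of exposed subjects such that
#' \deqn{r = \frac{a\pi/(a\pi + b(1-\pi))}{(1-a)\pi/((1-a)\pi + (1-b)(1-\pi))}.}
#'
#' @param pi Exposure probability (vectorized), each in (0, 1).
#' @param b Missingness probability given X = 0, in (0, 1).
#' @param target_r Target ratio in (0, 1].
#' @return A list with `a` (same length as `pi`) and `b`.
#' @export
solve_missingness_rates <- function(pi, b, target_r) {
  if (any(pi <= 0 | pi >= 1)) stop("pi must lie in (0, 1)", call. = FALSE)
  if (b <= 0 || b >= 1) stop("b must lie in (0, 1)", call. = FALSE)
  if (target_r <= 0 || target_r > 1) {
    stop("target_r must lie in (0, 1]", call. = FALSE)
  }
  ratio <- function(a) {
    p_miss <- a * pi / (a * pi + b * (1 - pi))
    p_obs <- (1 - a) * pi / ((1 - a) * pi + (1 - b) * (1 - pi))
    p_miss / p_obs
  }
  # r(a) increases from 0 at a = 0 through 1 at a = b, so for target_r in
  # (0, 1] the root lies in (0, b]
  lo <- rep(1e-14, length(pi))
  hi <- rep(b, length(pi))
  if (any(ratio(hi) < target_r - 1e-9)) {
    stop(sprintf("no root: feasible r range for b = %g is (0, 1]", b), call. = FALSE)
  }
  for (i in seq_len(80)) {
    mid <- (lo + hi) / 2
    too_low <- ratio(mid) < target_r
    lo[too_low] <- mid[too_low]
    hi[!too_low] <- mid[!too_low]
  }
  list(a = (lo + hi) / 2, b = b)
}

#' Empirical sensitivity ratio of a simulated cohort
#'
#' The ratio of true-exposure prevalence in the missing-exposure group to
#' that in the observed group, computed from the truth columns.  With
#' `strata`, the ratio is computed within each covariate stratum and averaged
#' weighted by stratum size (matching the covariate-conditional definition of
#' the sensitivity ratio).
#'
#' @param table A simulated cohort with `truth_x` and `missing_indicator`.
#' @param strata Optional character vector of covariate columns defining the
#'   conditioning strata.
#' @return The empirical ratio (scalar).
#' @export
empirical_r <- function(table, strata = NULL) {
  if (!all(c("truth_x", "missing_indicator") %in% names(table))) {
    stop("empirical_r needs truth columns (simulated data only)", call. = FALSE)
  }
  compute <- function(df) {
    miss <- df$missing_indicator == 1
    if (!any(miss) || all(miss)) {
      stop("empirical_r: both missing and non-missing groups must be nonempty",
           call. = FALSE)
    }
    p_miss <- mean(df$truth_x[miss])
    p_obs <- mean(df$truth_x[!miss])
    if (p_obs == 0) return(NA_real_)
    p_miss / p_obs
  }
  if (is.null(strata)) return(compute(table))
  groups <- interaction(table[strata], drop = TRUE)
  vals <- tapply(seq_len(nrow(table)), groups, function(idx) {
    df <- table[idx, ]
    miss <- df$missing_indicator == 1
    if (!any(miss) || all(miss) || mean(df$truth_x[!miss]) == 0) return(c(NA_real_, 0))
    c(mean(df$truth_x[miss]) / mean(df$truth_x[!miss]), length(idx))
  })
  vals <- do.call(rbind, vals)
  ok <- !is.na(vals[, 1])
  if (!any(ok)) stop("empirical_r: no usable stratum", call. = FALSE)
  sum(vals[ok, 1] * vals[ok, 2]) / sum(vals[ok, 2])
}

#' Parameter-recovery experiment
#'
#' Simulates `n_reps` cohorts (per-replicate seeds `config$seed + rep`), fits
#' the EM model to each, and summarizes recovery of the true exposure log
#' odds ratio: mean estimate, bias, empirical SE, nominal-95% Wald CI
#' coverage, and the complete-case comparison fit (tested subjects only).
#'
#' @param config A [simulation_config()].
#' @param n_reps Number of replicates (>= 2).
#' @param settings An [em_settings()]; `settings$r` is the analysis r.
#' @param spec Optional [model_spec()]; defaults to the correctly specified
#'   model implied by the config.
#' @return A one-row tibble summary with the per-replicate results attached
#'   as attribute `"reps"`.
#' @export
recovery_experiment <- function(config, n_reps, settings = em_settings(),
                                spec = NULL) {
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  z_terms <- vapply(config$covariates, `[[`, "", "name")
  w_terms <- vapply(config$confounders, `[[`, "", "name")
  spec <- spec %||% model_spec(c("exposure", w_terms, "gender"), z_terms)
  truth <- unname(config$beta["exposure"])
  reps <- purrr::map_dfr(seq_len(n_reps), function(i) {
    tab <- simulate_cohort(config, seed = config$seed + i)
    fit <- tryCatch(fit_em(tab, spec, settings), error = function(e) NULL)
    cc <- complete_case_estimate(tab, spec)
    if (is.null(fit)) {
      return(tibble::tibble(rep = i, converged = FALSE, estimate = NA_real_,
                            std.error = NA_real_, covered = NA,
                            cc_estimate = cc))
    }
    eff <- effect_estimate(fit, "exposure")
    tibble::tibble(
      rep = i, converged = fit$converged,
      estimate = eff$estimate, std.error = eff$std.error,
      covered = eff$estimate - wald_z_crit * eff$std.error <= truth &
        truth <= eff$estimate + wald_z_crit * eff$std.error,
      cc_estimate = cc
    )
  })
  used <- reps[reps$converged & !is.na(reps$estimate), ]
  n_failed <- n_reps - nrow(used)
  if (n_failed > 0) {
    message(sprintf("recovery_experiment: %d replicate(s) failed to converge and were excluded",
                    n_failed))
  }
  out <- tibble::tibble(
    n_reps = n_reps, n_used = nrow(used), true_log_or = truth,
    mean_estimate = mean(used$estimate), bias = mean(used$estimate) - truth,
    empirical_se = stats::sd(used$estimate),
    mean_model_se = mean(used$std.error),
    coverage = mean(used$covered),
    cc_mean_estimate = mean(used$cc_estimate, na.rm = TRUE),
    cc_bias = mean(used$cc_estimate, na.rm = TRUE) - truth
  )
  attr(out, "reps") <- reps
  out
}

# Complete-case exposure log-OR: outcome model fitted to tested subjects only.
complete_case_estimate <- function(table, spec) {
  sub <- table[table$hypoxia != "unknown", , drop = FALSE]
  attr(sub, "schema") <- attr(table, "schema")
  data <- tryCatch(prepare_em_data(sub, spec), error = function(e) NULL)
  if (is.null(data)) return(NA_real_)
  fit <- tryCatch(
    fit_weighted_logistic(data$y[!data$is_miss], observed_outcome_design(data)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NA_real_)
  unname(fit$coefficients["exposure"])
}
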