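# The EM estimator is validated against independent routes throughout:
# stats::glm on complete data, direct numerical maximization of the
# observed-data likelihood, derivative-free maximization of the tilted
# exposure objective, and hand-evaluated Bayes arithmetic for the E step.

make_em_instance <- function(n = 200, seed = 2, miss_rate = 0.4) {
  small_instance(n, seed = seed,
                 missingness = missingness_spec("mcar", rate = miss_rate))
}

test_that("model_spec validates its terms", {
  expect_error(model_spec(c("ses")), "exactly once")
  expect_error(model_spec(c("exposure", "exposure")), "exactly once")
  expect_error(model_spec(c("exposure", "ses", "ses")), "duplicated")
  expect_error(model_spec(c("exposure", "gender:exposure")), "main effect")
  expect_error(model_spec("exposure", c("smoking", "exposure")), "covariates")
  expect_error(em_settings(r = 1.2), "r must")
})

test_that("E-step weights follow Bayes' rule", {
  # 1 missing record with known prior and outcome likelihoods, plus two
  # observed records to keep the exposure model identifiable
  tab <- tibble::tibble(
    id = c("m", "p", "n"),
    gender = factor(rep("male", 3), c("male", "female")),
    asd = c(1L, 0L, 0L),
    hypoxia = factor(c("unknown", "positive", "negative"),
                     c("positive", "negative", "unknown"))
  )
  attr(tab, "schema") <- cohort_schema()
  spec <- model_spec("exposure")
  beta <- c("(Intercept)" = stats::qlogis(0.01), exposure = log(2))
  gamma <- c("(Intercept)" = stats::qlogis(0.2))
  # direct Bayes arithmetic oracle
  p1 <- 0.5 * 0.2
  f1 <- stats::plogis(stats::qlogis(0.01) + log(2))
  f0 <- 0.01
  expect_equal(e_step(tab, spec, beta, gamma, r = 0.5),
               p1 * f1 / (p1 * f1 + (1 - p1) * f0), tolerance = 1e-12)
  # r = 0 gives zero weight exactly
  expect_equal(e_step(tab, spec, beta, gamma, r = 0), 0)
  # null exposure effect makes the weight the prior r * pi
  beta0 <- c("(Intercept)" = stats::qlogis(0.01), exposure = 0)
  expect_equal(e_step(tab, spec, beta0, gamma, r = 0.5), p1, tolerance = 1e-12)
})

test_that("with no missing exposure the M step equals independent ML fits", {
  tab <- make_em_instance(300, seed = 4, miss_rate = 0.4)
  schema <- attr(tab, "schema")
  tab <- tab[tab$hypoxia != "unknown", ]
  attr(tab, "schema") <- schema
  spec <- quick_spec()
  fit <- m_step(tab, spec, weights = numeric(0), r = 1)
  x <- as.numeric(tab$hypoxia == "positive")
  glm_y <- stats::glm(tab$asd ~ x + (tab$ses == "mid") + (tab$ses == "high") +
                        (tab$gender == "male"), family = stats::binomial())
  glm_x <- stats::glm(x ~ (tab$smoking == "1") + (tab$parity == "1") +
                        (tab$parity == "2+"), family = stats::binomial())
  expect_equal(unname(fit$beta), unname(stats::coef(glm_y)), tolerance = 1e-6)
  expect_equal(unname(fit$gamma), unname(stats::coef(glm_x)), tolerance = 1e-6)
})

test_that("at r = 1 the tilted exposure M step is a weighted logistic fit", {
  tab <- make_em_instance(250, seed = 5)
  spec <- quick_spec()
  beta <- c("(Intercept)" = -1, exposure = 0.5, "ses=mid" = 0, "ses=high" = 0,
            "gender=male" = 0.3)
  gamma <- c("(Intercept)" = -1.5, "smoking=1" = 0.4, "parity=1" = 0,
             "parity=2+" = -0.2)
  w <- e_step(tab, spec, beta, gamma, r = 1)
  upd <- m_step(tab, spec, w, r = 1)
  # pseudo-record weighted logistic oracle for gamma
  enc <- encode_design(tab, c("smoking", "parity"))
  obs <- tab$hypoxia != "unknown"
  Z <- enc$design
  design <- rbind(Z[obs, ], Z[!obs, ], Z[!obs, ])
  yx <- c(as.numeric(tab$hypoxia[obs] == "positive"),
          rep(1, sum(!obs)), rep(0, sum(!obs)))
  wts <- c(rep(1, sum(obs)), w, 1 - w)
  oracle <- fit_weighted_logistic(yx, design, wts)
  expect_equal(upd$gamma, oracle$coefficients, tolerance = 1e-8)
})

test_that("at r < 1 the exposure M step matches a derivative-free optimizer", {
  tab <- make_em_instance(120, seed = 6)
  spec <- quick_spec()
  beta <- c("(Intercept)" = -1, exposure = 0.4, "ses=mid" = 0.1,
            "ses=high" = -0.1, "gender=male" = 0.2)
  gamma <- c("(Intercept)" = -1.4, "smoking=1" = 0.3, "parity=1" = -0.1,
             "parity=2+" = -0.3)
  r <- 0.5
  w <- e_step(tab, spec, beta, gamma, r = r)
  upd <- m_step(tab, spec, w, r = r)
  # independent tilted objective, maximized by Nelder-Mead
  enc <- encode_design(tab, c("smoking", "parity"))
  obs <- tab$hypoxia != "unknown"
  Z <- enc$design
  x_obs <- as.numeric(tab$hypoxia[obs] == "positive")
  q_fn <- function(g) {
    pi_all <- stats::plogis(drop(Z %*% g))
    sum(x_obs * log(pi_all[obs]) + (1 - x_obs) * log(1 - pi_all[obs])) +
      sum(w * log(r * pi_all[!obs]) + (1 - w) * log(1 - r * pi_all[!obs]))
  }
  opt <- stats::optim(unname(gamma), function(g) -q_fn(g), method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
  opt <- stats::optim(opt$par, function(g) -q_fn(g), method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
  expect_equal(unname(upd$gamma), opt$par, tolerance = 1e-4)
})

test_that("observed-data likelihood reduces to the two sub-model likelihoods", {
  tab <- make_em_instance(200, seed = 7)
  complete <- tab[tab$hypoxia != "unknown", ]
  attr(complete, "schema") <- attr(tab, "schema")
  spec <- quick_spec()
  fit <- m_step(complete, spec, numeric(0), r = 1)
  x <- as.numeric(complete$hypoxia == "positive")
  glm_y <- stats::glm(complete$asd ~ x + (complete$ses == "mid") +
                        (complete$ses == "high") + (complete$gender == "male"),
                      family = stats::binomial())
  glm_x <- stats::glm(x ~ (complete$smoking == "1") + (complete$parity == "1") +
                        (complete$parity == "2+"), family = stats::binomial())
  expect_equal(observed_loglik(complete, spec, fit$beta, fit$gamma, r = 1),
               as.numeric(stats::logLik(glm_y)) + as.numeric(stats::logLik(glm_x)),
               tolerance = 1e-6)
})

test_that("a missing record contributes a hand-summed two-term mixture", {
  tab <- tibble::tibble(
    id = c("m", "p", "n"),
    gender = factor(rep("male", 3), c("male", "female")),
    asd = c(1L, 1L, 0L),
    hypoxia = factor(c("unknown", "positive", "negative"),
                     c("positive", "negative", "unknown"))
  )
  attr(tab, "schema") <- cohort_schema()
  spec <- model_spec("exposure")
  beta <- c("(Intercept)" = -2, exposure = 0.7)
  gamma <- c("(Intercept)" = -1)
  r <- 0.6
  pi <- stats::plogis(-1)
  mu1 <- stats::plogis(-2 + 0.7)
  mu0 <- stats::plogis(-2)
  by_hand <-
    log(mu1) + log(pi) +                    # observed exposed case
    log(1 - mu0) + log(1 - pi) +            # observed unexposed non-case
    log(r * pi * mu1 + (1 - r * pi) * mu0)  # missing case: two-term mixture
  expect_equal(observed_loglik(tab, spec, beta, gamma, r = r), by_hand,
               tolerance = 1e-12)
})

test_that("a degenerate exposure prior makes the missing term r-invariant", {
  tab <- tibble::tibble(
    id = c("m", "p", "n"),
    gender = factor(rep("female", 3), c("male", "female")),
    asd = c(1L, 1L, 0L),
    hypoxia = factor(c("unknown", "positive", "negative"),
                     c("positive", "negative", "unknown"))
  )
  attr(tab, "schema") <- cohort_schema()
  spec <- model_spec("exposure")
  beta <- c("(Intercept)" = -2, exposure = 0.7)
  gamma <- c("(Intercept)" = -40)  # pi numerically zero
  lls <- vapply(c(0, 0.3, 1), function(r)
    observed_loglik(tab, spec, beta, gamma, r), numeric(1))
  expect_equal(max(lls) - min(lls), 0, tolerance = 1e-9)
})

test_that("EM with zero missing exposures is a one-step fixed point", {
  tab <- make_em_instance(300, seed = 8)
  complete <- tab[tab$hypoxia != "unknown", ]
  attr(complete, "schema") <- attr(tab, "schema")
  spec <- quick_spec()
  fit <- fit_em(complete, spec, em_settings(r = 1))
  expect_true(fit$converged)
  expect_equal(fit$n_iter, 1L)
  direct <- m_step(complete, spec, numeric(0), r = 1)
  expect_equal(fit$beta, direct$beta, tolerance = 1e-8)
  expect_equal(fit$gamma, direct$gamma, tolerance = 1e-8)
})

test_that("complete-data covariance matches the standard logistic covariance", {
  tab <- make_em_instance(400, seed = 9)
  complete <- tab[tab$hypoxia != "unknown", ]
  attr(complete, "schema") <- attr(tab, "schema")
  spec <- quick_spec()
  fit <- fit_em(complete, spec, em_settings(r = 1))
  x <- as.numeric(complete$hypoxia == "positive")
  glm_y <- stats::glm(complete$asd ~ x + (complete$ses == "mid") +
                        (complete$ses == "high") + (complete$gender == "male"),
                      family = stats::binomial())
  vc <- stats::vcov(glm_y)
  block <- fit$covariance[seq_along(fit$beta), seq_along(fit$beta)]
  expect_equal(unname(block), unname(vc), tolerance = 1e-4)
})

test_that("EM equals direct maximization of the observed-data likelihood", {
  spec <- quick_spec()
  for (case in list(list(seed = 21, r = 0.5), list(seed = 22, r = 1))) {
    tab <- make_em_instance(250, seed = case$seed)
    fit <- fit_em(tab, spec, em_settings(r = case$r, tol = 1e-9,
                                         variance_method = "none"))
    theta0 <- c(fit$beta * 0, fit$gamma * 0)
    nb <- length(fit$beta)
    nll <- function(th) -observed_loglik(tab, spec, th[1:nb], th[-(1:nb)], case$r)
    opt <- stats::optim(theta0, nll, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-15))
    expect_equal(unname(c(fit$beta, fit$gamma)), unname(opt$par),
                 tolerance = 1e-4)
  }
})

test_that("EM trajectory is nondecreasing and weights stay in [0, 1]", {
  spec <- quick_spec()
  for (case in list(list(seed = 31, r = 0.2), list(seed = 32, r = 0.7),
                    list(seed = 33, r = 1))) {
    tab <- make_em_instance(300, seed = case$seed)
    fit <- fit_em(tab, spec, em_settings(r = case$r, variance_method = "none"))
    traj <- fit$loglik_trajectory
    expect_true(all(diff(traj) >= -1e-8 * abs(traj[-length(traj)])))
    expect_true(all(fit$weights >= 0 & fit$weights <= 1))
    expect_true(fit$converged)
    expect_lte(fit$n_iter, 500)
  }
})

test_that("unidentifiable exposure levels are refused", {
  tab <- make_em_instance(100, seed = 12)
  schema <- attr(tab, "schema")
  tab$hypoxia[tab$hypoxia == "negative"] <- "positive"
  attr(tab, "schema") <- schema
  expect_error(fit_em(tab, quick_spec()), "unidentifiable")
})

test_that("effect estimates transform coefficients by closed form", {
  fake <- structure(list(beta = c(exposure = 0),
                         covariance = matrix(0.01, 1, 1,
                                             dimnames = list("y.exposure", "y.exposure"))),
                    class = "em_fit")
  eff <- effect_estimate(fake, "exposure")
  expect_equal(eff$odds_ratio, 1)
  expect_equal(eff$p_value, 1)

  fake$beta <- c(exposure = 0.25)
  eff <- effect_estimate(fake, "exposure")
  expect_equal(eff$ci_low, exp(0.25 - 1.959964 * 0.1), tolerance = 1e-9)
  expect_equal(eff$ci_high, exp(0.25 + 1.959964 * 0.1), tolerance = 1e-9)

  fake$beta <- c(exposure = log(2))
  fake$covariance[1, 1] <- 0
  eff <- effect_estimate(fake, "exposure")
  expect_equal(c(eff$ci_low, eff$ci_high), c(2, 2))
  expect_error(effect_estimate(fake, "bananas"), "unknown")
})

test_that("saturated complete-data interaction equals the ratio of sample ORs", {
  counts <- c(m11 = 30, m10 = 60, m01 = 25, m00 = 85,
              f11 = 15, f10 = 70, f01 = 20, f00 = 95)
  cells <- expand.grid(sex = c("m", "f"), x = c(1, 0), y = c(1, 0),
                       stringsAsFactors = FALSE)
  cells$n <- counts[paste0(cells$sex, cells$x, cells$y)]
  rows <- cells[rep(seq_len(nrow(cells)), cells$n), ]
  tab <- tibble::tibble(
    id = as.character(seq_len(nrow(rows))),
    gender = factor(ifelse(rows$sex == "m", "male", "female"), c("male", "female")),
    asd = as.integer(rows$y),
    hypoxia = factor(ifelse(rows$x == 1, "positive", "negative"),
                     c("positive", "negative", "unknown"))
  )
  attr(tab, "schema") <- cohort_schema()
  spec <- model_spec(c("exposure", "gender", "gender:exposure"))
  est <- interaction_fit(tab, spec, em_settings(r = 1))
  or_m <- (counts["m11"] / counts["m10"]) / (counts["m01"] / counts["m00"])
  or_f <- (counts["f11"] / counts["f10"]) / (counts["f01"] / counts["f00"])
  expect_equal(est$odds_ratio, unname(or_m / or_f), tolerance = 1e-6)
  expect_error(interaction_fit(tab[tab$gender == "male", ], spec),
               "both genders")
})

test_that("bootstrap variance needs at least two replicates and broadly
           agrees with the observed-information variance", {
  tab <- make_em_instance(400, seed = 14)
  spec <- quick_spec()
  fit <- fit_em(tab, spec, em_settings(r = 1))
  expect_error(em_variance(fit, tab, em_settings(variance_method = "bootstrap",
                                                 bootstrap_reps = 1)),
               "at least 2")
  boot <- em_variance(fit, tab, em_settings(variance_method = "bootstrap",
                                            bootstrap_reps = 40, seed = 2))
  i <- which(names(fit$beta) == "exposure")
  expect_lt(abs(log(sqrt(boot[i, i]) / sqrt(fit$covariance[i, i]))), log(2))
})

test_that("tidy and glance summarize a fit consistently", {
  tab <- make_em_instance(300, seed = 16)
  fit <- fit_em(tab, quick_spec(), em_settings(r = 0.7))
  td <- tidy(fit)
  expect_equal(nrow(td), length(fit$beta) + length(fit$gamma))
  expect_true(all(c("model", "term", "estimate", "std.error", "p.value") %in%
                    names(td)))
  expect_equal(td$estimate[td$term == "exposure" & td$model == "outcome"],
               unname(fit$beta["exposure"]))
  or <- tidy(fit, exponentiate = TRUE)
  expect_equal(or$estimate, exp(td$estimate))
  gl <- glance(fit)
  expect_equal(gl$r, 0.7)
  expect_equal(gl$n_missing, fit$n_missing)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
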