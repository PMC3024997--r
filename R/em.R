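# EM estimator for the joint likelihood P(Y | X, W) * P(X | Z) with the binary
# exposure X missing for a fraction of subjects.  Missing exposures enter the
# likelihood through two fractionally weighted pseudo-records (X = 1 with
# weight w, X = 0 with weight 1 - w).  Under the not-missing-at-random
# mechanism, untested subjects carry exposure probability r * pi(Z), where
# pi(Z) is the exposure probability of tested subjects with the same
# covariates and r in [0, 1] is a fixed sensitivity ratio (r = 1 <=> MAR).

#' Specify the outcome and exposure models
#'
#' @param outcome_terms Character vector of terms for the outcome model
#'   P(Y | X, W).  Must contain `"exposure"` exactly once; may contain
#'   `"gender"` (male indicator), `"gender:exposure"` (effect-modification
#'   product term, requires `"gender"`), and names of schema covariates
#'   (confounders W).
#' @param exposure_terms Character vector of schema covariate names (Z) for
#'   the exposure model P(X | Z); may be empty (intercept-only).
#' @return A list of class `model_spec`.
#' @examples
#' model_spec(c("exposure", "birth_year", "ses"), c("maternal_age", "parity"))
#' @export
model_spec <- function(outcome_terms, exposure_terms = character()) {
  if (sum(outcome_terms == "exposure") != 1) {
    stop("outcome_terms must contain 'exposure' exactly once", call. = FALSE)
  }
  if (anyDuplicated(outcome_terms) || anyDuplicated(exposure_terms)) {
    stop("duplicated model terms", call. = FALSE)
  }
  if ("gender:exposure" %in% outcome_terms && !"gender" %in% outcome_terms) {
    stop("'gender:exposure' requires the 'gender' main effect", call. = FALSE)
  }
  if (any(c("exposure", "gender:exposure") %in% exposure_terms)) {
    stop("exposure_terms may only contain covariates (and 'gender')", call. = FALSE)
  }
  structure(list(outcome_terms = outcome_terms,
                 exposure_terms = as.character(exposure_terms)),
            class = "model_spec")
}

#' EM estimation settings
#'
#' @param r Sensitivity ratio in \[0, 1\]: the ratio of the
#'   covariate-conditional exposure probability in the missing-exposure group
#'   to that in the tested group.  `r = 1` is the missing-at-random analysis.
#' @param tol Convergence tolerance on the parameter sup-norm change.
#' @param max_iter Maximum EM iterations.
#' @param variance_method `"observed_hessian"` (numerically differentiated
#'   Hessian of the observed-data log-likelihood), `"bootstrap"`, or `"none"`
#'   (point estimates only; no intervals or p-values).
#' @param bootstrap_reps Bootstrap replicates when `variance_method =
#'   "bootstrap"`.
#' @param seed Seed for the bootstrap resampler.
#' @return A list of class `em_settings`.
#' @export
em_settings <- function(r = 1, tol = 1e-6, max_iter = 500,
                        variance_method = c("observed_hessian", "bootstrap", "none"),
                        bootstrap_reps = 200, seed = 1L) {
  if (r < 0 || r > 1) stop("r must lie in [0, 1]", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  structure(list(r = r, tol = tol, max_iter = as.integer(max_iter),
                 variance_method = match.arg(variance_method),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed)),
            class = "em_settings")
}

# ---- design assembly ---------------------------------------------------------

covariate_terms <- function(terms) {
  setdiff(terms, c("exposure", "gender", "gender:exposure"))
}

# Build the outcome design for a fixed exposure value x (0 or 1) on the kept
# rows.  Term order follows the user's listing; intercept always first.
build_outcome_design <- function(table, rows, terms, schema, x) {
  n <- length(rows)
  male <- as.numeric(table$gender[rows] == "male")
  blocks <- lapply(terms, function(term) {
    if (term == "exposure") {
      matrix(rep_len(x, n), ncol = 1, dimnames = list(NULL, "exposure"))
    } else if (term == "gender") {
      matrix(male, ncol = 1, dimnames = list(NULL, "gender=male"))
    } else if (term == "gender:exposure") {
      matrix(male * rep_len(x, n), ncol = 1, dimnames = list(NULL, "gender=male:exposure"))
    } else {
      cats <- schema[[term]]
      vals <- as.character(table[[term]][rows])
      block <- vapply(cats[-1], function(lvl) as.numeric(vals == lvl), numeric(n))
      matrix(block, nrow = n, dimnames = list(NULL, paste0(term, "=", cats[-1])))
    }
  })
  do.call(cbind, c(list(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))),
                   blocks))
}

# Validate the table against the model spec and precompute every matrix the EM
# loop needs.  Complete-case in all requested covariates, with a reported count.
prepare_em_data <- function(table, spec, schema = get_schema(table)) {
  stopifnot(inherits(spec, "model_spec"))
  cov_terms <- union(covariate_terms(spec$outcome_terms), spec$exposure_terms)
  missing_terms <- setdiff(cov_terms, names(schema))
  if (length(missing_terms)) {
    stop(sprintf("term(s) not in schema: %s", paste(missing_terms, collapse = ", ")),
         call. = FALSE)
  }
  uses_gender <- any(c("gender", "gender:exposure") %in% spec$outcome_terms)
  keep <- !is.na(table$asd) & !is.na(table$hypoxia)
  if (uses_gender) keep <- keep & !is.na(table$gender)
  for (nm in cov_terms) keep <- keep & !is.na(table[[nm]])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("fit_em: excluded %d record(s) with absent covariate values",
                    n_dropped))
  }
  rows <- which(keep)
  hyp <- as.character(table$hypoxia[rows])
  is_miss <- hyp == "unknown"
  x_obs <- as.numeric(hyp[!is_miss] == "positive")
  if (length(unique(x_obs)) < 2) {
    stop("exposure model unidentifiable: need both exposure levels among tested subjects",
         call. = FALSE)
  }
  X1 <- build_outcome_design(table, rows, spec$outcome_terms, schema, 1)
  X0 <- build_outcome_design(table, rows, spec$outcome_terms, schema, 0)
  z_enc <- build_outcome_design(table, rows, spec$exposure_terms, schema, 0)
  Xz <- z_enc[, setdiff(colnames(z_enc), c("exposure")), drop = FALSE]
  list(
    y = table$asd[rows], is_miss = is_miss, x_obs = x_obs,
    X1 = X1, X0 = X0, Xz = Xz,
    n = length(rows), n_miss = sum(is_miss), n_dropped = n_dropped,
    beta_names = colnames(X1), gamma_names = colnames(Xz)
  )
}

# Outcome design rows at the observed exposure values.
observed_outcome_design <- function(data) {
  obs <- !data$is_miss
  X <- data$X0[obs, , drop = FALSE]
  pos <- data$x_obs == 1
  X[pos, ] <- data$X1[obs, , drop = FALSE][pos, ]
  X
}

# ---- E step ------------------------------------------------------------------

.e_step <- function(data, beta, gamma, r) {
  if (data$n_miss == 0) return(numeric(0))
  miss <- data$is_miss
  pi_z <- clip_prob(logistic(drop(data$Xz[miss, , drop = FALSE] %*% gamma)))
  p1 <- r * pi_z
  stopifnot(all(p1 <= 1))  # guaranteed for r <= 1; guarded anyway
  y <- data$y[miss]
  mu1 <- clip_prob(logistic(drop(data$X1[miss, , drop = FALSE] %*% beta)))
  mu0 <- clip_prob(logistic(drop(data$X0[miss, , drop = FALSE] %*% beta)))
  f1 <- ifelse(y == 1, mu1, 1 - mu1)
  f0 <- ifelse(y == 1, mu0, 1 - mu0)
  p1 * f1 / (p1 * f1 + (1 - p1) * f0)
}

#' E step: posterior exposure probabilities for missing-exposure records
#'
#' For each record with unknown exposure, computes the posterior probability
#' that X = 1 given its outcome and covariates under the current parameters:
#' the prior is `r * pi(Z)` and Bayes' rule folds in the outcome likelihood
#' under X = 1 versus X = 0.  Records with observed exposure are untouched.
#'
#' @param table A cohort tibble.
#' @param spec A [model_spec()].
#' @param beta,gamma Current outcome- and exposure-model coefficients (aligned
#'   to the designs built by the spec; see [fit_em()]).
#' @param r Sensitivity ratio in \[0, 1\].
#' @return Numeric vector of fractional weights, one per missing-exposure
#'   record (in table order).
#' @export
e_step <- function(table, spec, beta, gamma, r = 1) {
  .e_step(prepare_em_data(table, spec), beta, gamma, r)
}

# ---- M step ------------------------------------------------------------------

# Maximize the tilted exposure objective
#   Q(gamma) = sum_obs [x log pi + (1-x) log(1-pi)]
#            + sum_miss [w log(r pi) + (1-w) log(1 - r pi)]
# by Newton with step-halving; ridge fallback if the Hessian is indefinite.
# For r = 1 this is exactly a weighted logistic fit on the pseudo-records.
fit_gamma_tilted <- function(x_obs, Z_obs, Z_miss, w, r, start = NULL,
                             grad_tol = 1e-8, max_iter = 100) {
  p <- ncol(Z_obs)
  gamma <- start %||% numeric(p)
  q_value <- function(g) {
    pi_o <- clip_prob(logistic(drop(Z_obs %*% g)))
    q <- sum(x_obs * log(pi_o) + (1 - x_obs) * log(1 - pi_o))
    if (length(w)) {
      pi_m <- clip_prob(logistic(drop(Z_miss %*% g)))
      s <- clip_prob(r * pi_m)
      q <- q + sum(w * log(s) + (1 - w) * log(1 - s))
    }
    q
  }
  q <- q_value(gamma)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    pi_o <- clip_prob(logistic(drop(Z_obs %*% gamma)))
    grad <- drop(crossprod(Z_obs, x_obs - pi_o))
    hess_w <- pi_o * (1 - pi_o)
    H <- -crossprod(Z_obs, Z_obs * hess_w)
    if (length(w)) {
      pi_m <- clip_prob(logistic(drop(Z_miss %*% gamma)))
      s <- clip_prob(r * pi_m)
      g_m <- w * (1 - pi_m) - (1 - w) * s * (1 - pi_m) / (1 - s)
      grad <- grad + drop(crossprod(Z_miss, g_m))
      h_m <- w * pi_m * (1 - pi_m) +
        (1 - w) * s * (1 - pi_m) *
          ((1 - s) * (1 - 2 * pi_m) + s * (1 - pi_m)) / (1 - s)^2
      H <- H - crossprod(Z_miss, Z_miss * h_m)
    }
    if (max(abs(grad)) <= grad_tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(-H, grad), error = function(e) NULL)
    ridge <- 1e-6
    while (is.null(step) ||
           (length(w) && drop(crossprod(step, grad)) <= 0)) {
      step <- tryCatch(solve(-H + diag(ridge, p), grad), error = function(e) NULL)
      ridge <- ridge * 10
      if (ridge > 1e6) stop("exposure M-step Hessian irreparably singular", call. = FALSE)
    }
    lambda <- 1
    for (h in seq_len(25)) {
      cand <- gamma + lambda * step
      q_cand <- q_value(cand)
      if (q_cand >= q - 1e-12) break
      lambda <- lambda / 2
    }
    gamma <- cand
    q <- q_cand
  }
  names(gamma) <- colnames(Z_obs)
  list(gamma = gamma, q = q, converged = converged)
}

.m_step <- function(data, weights, r, beta_start = NULL, gamma_start = NULL) {
  obs <- !data$is_miss
  X_obs <- observed_outcome_design(data)
  if (data$n_miss > 0) {
    design <- rbind(X_obs,
                    data$X1[data$is_miss, , drop = FALSE],
                    data$X0[data$is_miss, , drop = FALSE])
    y <- c(data$y[obs], data$y[data$is_miss], data$y[data$is_miss])
    w <- c(rep(1, sum(obs)), weights, 1 - weights)
  } else {
    design <- X_obs
    y <- data$y[obs]
    w <- rep(1, sum(obs))
  }
  beta_fit <- fit_weighted_logistic(y, design, w, start = beta_start)
  gamma_fit <- fit_gamma_tilted(data$x_obs, data$Xz[obs, , drop = FALSE],
                                data$Xz[data$is_miss, , drop = FALSE],
                                weights, r, start = gamma_start)
  list(beta = beta_fit$coefficients, gamma = gamma_fit$gamma)
}

#' M step: weighted maximization of both sub-models
#'
#' Refits the outcome model on the pseudo-record expansion (observed-exposure
#' records with weight 1; each missing-exposure record as X = 1 with weight
#' `w` and X = 0 with weight `1 - w`) and maximizes the tilted exposure
#' objective in which missing records contribute `w log(r pi) + (1 - w)
#' log(1 - r pi)`.
#'
#' @inheritParams e_step
#' @param weights Fractional weights from [e_step()].
#' @return A list with updated `beta` and `gamma`.
#' @export
m_step <- function(table, spec, weights, r = 1) {
  .m_step(prepare_em_data(table, spec), weights, r)
}

# ---- observed-data likelihood ------------------------------------------------

.observed_loglik <- function(data, beta, gamma, r) {
  obs <- !data$is_miss
  X_obs <- observed_outcome_design(data)
  mu_obs <- clip_prob(logistic(drop(X_obs %*% beta)))
  y_o <- data$y[obs]
  pi_o <- clip_prob(logistic(drop(data$Xz[obs, , drop = FALSE] %*% gamma)))
  ll <- sum(y_o * log(mu_obs) + (1 - y_o) * log(1 - mu_obs)) +
    sum(data$x_obs * log(pi_o) + (1 - data$x_obs) * log(1 - pi_o))
  if (data$n_miss > 0) {
    miss <- data$is_miss
    y_m <- data$y[miss]
    pi_m <- clip_prob(logistic(drop(data$Xz[miss, , drop = FALSE] %*% gamma)))
    p1 <- r * pi_m
    mu1 <- clip_prob(logistic(drop(data$X1[miss, , drop = FALSE] %*% beta)))
    mu0 <- clip_prob(logistic(drop(data$X0[miss, , drop = FALSE] %*% beta)))
    f1 <- ifelse(y_m == 1, mu1, 1 - mu1)
    f0 <- ifelse(y_m == 1, mu0, 1 - mu0)
    ll <- ll + sum(log(p1 * f1 + (1 - p1) * f0))
  }
  ll
}

#' Observed-data log-likelihood
#'
#' The likelihood with the missing exposure summed out: observed-exposure
#' records contribute both sub-models directly; each missing-exposure record
#' contributes the two-component mixture
#' `log(f(Y | X = 1) r pi + f(Y | X = 0) (1 - r pi))`.  This is the objective
#' the EM algorithm maximizes.
#'
#' @inheritParams e_step
#' @return Scalar log-likelihood.
#' @export
observed_loglik <- function(table, spec, beta, gamma, r = 1) {
  .observed_loglik(prepare_em_data(table, spec), beta, gamma, r)
}

# ---- EM driver ---------------------------------------------------------------

#' Fit the missing-exposure model by EM
#'
#' Initializes both sub-models by complete-case fits on tested subjects, then
#' alternates [e_step()] and [m_step()] until the parameter sup-norm change
#' falls below `settings$tol` or `settings$max_iter` is reached.  The
#' observed-data log-likelihood is recorded every iteration (it is
#' nondecreasing for any fixed `r`).  The joint covariance of `(beta, gamma)`
#' is computed by the method in `settings` (see [em_variance()]).
#'
#' @param table A cohort tibble (see [read_cohort()] / [simulate_cohort()]).
#' @param spec A [model_spec()].
#' @param settings An [em_settings()].
#' @param init Optional list with named `beta` and `gamma` start values
#'   (e.g. a previous fit), replacing the complete-case initialization.
#' @return An object of class `em_fit` with elements `beta`, `gamma`,
#'   `covariance`, `loglik_trajectory`, `weights` (posterior P(X = 1) per
#'   missing record), `n_iter`, `converged`, plus bookkeeping.  Supports
#'   [generics::tidy()], [generics::glance()], `autoplot()`.
#' @export
fit_em <- function(table, spec, settings = em_settings(), init = NULL) {
  data <- prepare_em_data(table, spec)
  r <- settings$r
  obs <- !data$is_miss
  if (is.null(init)) {
    beta <- fit_weighted_logistic(data$y[obs], observed_outcome_design(data))$coefficients
    gamma <- fit_weighted_logistic(data$x_obs, data$Xz[obs, , drop = FALSE])$coefficients
  } else {
    stopifnot(identical(names(init$beta), data$beta_names),
              identical(names(init$gamma), data$gamma_names))
    beta <- init$beta
    gamma <- init$gamma
  }
  trajectory <- .observed_loglik(data, beta, gamma, r)
  converged <- FALSE
  n_iter <- 0L
  weights <- numeric(0)
  repeat {
    n_iter <- n_iter + 1L
    weights <- .e_step(data, beta, gamma, r)
    upd <- .m_step(data, weights, r, beta_start = beta, gamma_start = gamma)
    delta <- max(abs(c(upd$beta - beta, upd$gamma - gamma)))
    beta <- upd$beta
    gamma <- upd$gamma
    trajectory <- c(trajectory, .observed_loglik(data, beta, gamma, r))
    if (delta < settings$tol) {
      converged <- TRUE
      break
    }
    if (n_iter >= settings$max_iter) break
  }
  if (!converged) {
    warning(sprintf("EM did not converge in %d iterations (last sup-norm change %.3g)",
                    n_iter, delta), call. = FALSE)
  }
  fit <- structure(
    list(beta = beta, gamma = gamma, covariance = NULL,
         loglik_trajectory = trajectory,
         loglik = trajectory[length(trajectory)],
         weights = weights, n_iter = n_iter, converged = converged,
         settings = settings, spec = spec,
         n = data$n, n_missing = data$n_miss, n_dropped = data$n_dropped),
    class = "em_fit"
  )
  if (settings$variance_method != "none") {
    fit$covariance <- em_variance(fit, table, settings)
  }
  fit
}

# ---- variance ----------------------------------------------------------------

#' Covariance of the EM estimates
#'
#' `observed_hessian`: central-difference Hessian of the observed-data
#' log-likelihood at the optimum (step `1e-4 * (1 + |theta|)` per coordinate),
#' inverted with its sign flipped.  `bootstrap`: resample records with
#' replacement, refit, and take the empirical covariance across replicates
#' (seeded from `settings$seed`).
#'
#' @param fit A converged `em_fit`.
#' @param table The cohort tibble the fit was computed on.
#' @param settings An [em_settings()]; `variance_method` and, for the
#'   bootstrap, `bootstrap_reps` and `seed` are honoured.
#' @return Joint covariance matrix of `c(beta, gamma)` with row/column names
#'   prefixed `y.` (outcome model) and `x.` (exposure model).
#' @export
em_variance <- function(fit, table, settings = fit$settings) {
  data <- prepare_em_data(table, fit$spec)
  theta <- c(fit$beta, fit$gamma)
  nm <- c(paste0("y.", names(fit$beta)), paste0("x.", names(fit$gamma)))
  if (settings$variance_method != "bootstrap") {
    pb <- length(fit$beta)
    f <- function(th) .observed_loglik(data, th[seq_len(pb)], th[-seq_len(pb)],
                                       settings$r)
    H <- central_hessian(f, theta)
    cov <- tryCatch(solve(-H), error = function(e) {
      stop("observed-information matrix is not invertible; consider variance_method = 'bootstrap'",
           call. = FALSE)
    })
  } else {
    if (settings$bootstrap_reps < 2) {
      stop("bootstrap variance needs at least 2 replicates", call. = FALSE)
    }
    set.seed(settings$seed)
    reps <- purrr::map(seq_len(settings$bootstrap_reps), function(i) {
      idx <- sample.int(nrow(table), replace = TRUE)
      boot <- table[idx, , drop = FALSE]
      attr(boot, "schema") <- attr(table, "schema")
      boot_settings <- settings
      boot_settings$variance_method <- "none"
      bfit <- tryCatch(fit_em_point(boot, fit$spec, boot_settings),
                       error = function(e) NULL)
      if (is.null(bfit)) NULL else c(bfit$beta, bfit$gamma)
    })
    reps <- reps[!vapply(reps, is.null, logical(1))]
    if (length(reps) < 2) stop("too few successful bootstrap refits", call. = FALSE)
    cov <- stats::cov(do.call(rbind, reps))
  }
  dimnames(cov) <- list(nm, nm)
  cov
}

# Point estimation only (no variance); used by the bootstrap.
fit_em_point <- function(table, spec, settings) {
  data <- prepare_em_data(table, spec)
  obs <- !data$is_miss
  beta <- fit_weighted_logistic(data$y[obs], observed_outcome_design(data))$coefficients
  gamma <- fit_weighted_logistic(data$x_obs, data$Xz[obs, , drop = FALSE])$coefficients
  for (i in seq_len(settings$max_iter)) {
    w <- .e_step(data, beta, gamma, settings$r)
    upd <- .m_step(data, w, settings$r, beta_start = beta, gamma_start = gamma)
    delta <- max(abs(c(upd$beta - beta, upd$gamma - gamma)))
    beta <- upd$beta
    gamma <- upd$gamma
    if (delta < settings$tol) break
  }
  list(beta = beta, gamma = gamma)
}

central_hessian <- function(f, theta, rel_step = 1e-4) {
  p <- length(theta)
  h <- rel_step * (1 + abs(theta))
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        tp <- theta; tp[i] <- theta[i] + h[i]
        tm <- theta; tm[i] <- theta[i] - h[i]
        H[i, i] <- (f(tp) - 2 * f(theta) + f(tm)) / h[i]^2
      } else {
        tpp <- theta; tpp[i] <- tpp[i] + h[i]; tpp[j] <- tpp[j] + h[j]
        tpm <- theta; tpm[i] <- tpm[i] + h[i]; tpm[j] <- tpm[j] - h[j]
        tmp <- theta; tmp[i] <- tmp[i] - h[i]; tmp[j] <- tmp[j] + h[j]
        tmm <- theta; tmm[i] <- tmm[i] - h[i]; tmm[j] <- tmm[j] - h[j]
        H[i, j] <- H[j, i] <- (f(tpp) - f(tpm) - f(tmp) + f(tmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

# ---- effects -----------------------------------------------------------------

#' Odds ratio, Wald confidence interval and p-value for a model term
#'
#' @param fit An `em_fit`.
#' @param term Name of an outcome-model coefficient (e.g. `"exposure"`,
#'   `"gender=male:exposure"`).
#' @return A one-row tibble: `term`, `estimate` (log odds ratio),
#'   `std.error`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`.
#' @export
effect_estimate <- function(fit, term = "exposure") {
  if (!term %in% names(fit$beta)) {
    stop(sprintf("unknown outcome-model term '%s'; available: %s",
                 term, paste(names(fit$beta), collapse = ", ")), call. = FALSE)
  }
  est <- unname(fit$beta[term])
  se <- if (is.null(fit$covariance)) NA_real_ else
    sqrt(fit$covariance[paste0("y.", term), paste0("y.", term)])
  if (is.na(se)) {
    return(tibble::tibble(term = term, estimate = est, std.error = NA_real_,
                          odds_ratio = exp(est), ci_low = NA_real_,
                          ci_high = NA_real_, p_value = NA_real_))
  }
  z <- if (se > 0) est / se else ifelse(est == 0, 0, sign(est) * Inf)
  tibble::tibble(
    term = term,
    estimate = est,
    std.error = se,
    odds_ratio = exp(est),
    ci_low = exp(est - wald_z_crit * se),
    ci_high = exp(est + wald_z_crit * se),
    p_value = 2 * stats::pnorm(-abs(z))
  )
}

#' Test effect modification of the exposure by gender
#'
#' Augments the outcome model with a gender main effect and a
#' gender-by-exposure product term (if not already present), fits the EM
#' model, and returns the Wald test of the product coefficient.  The
#' interaction odds ratio is the ratio of the male to the female exposure
#' odds ratio.
#'
#' @inheritParams fit_em
#' @return The [effect_estimate()] tibble for the product term, with the full
#'   `em_fit` attached as attribute `"fit"`.
#' @export
interaction_fit <- function(table, spec, settings = em_settings()) {
  if (length(unique(stats::na.omit(as.character(table$gender)))) < 2) {
    stop("interaction_fit requires both genders in the table", call. = FALSE)
  }
  terms <- spec$outcome_terms
  if (!"gender" %in% terms) terms <- c(terms, "gender")
  if (!"gender:exposure" %in% terms) terms <- c(terms, "gender:exposure")
  spec <- model_spec(terms, spec$exposure_terms)
  fit <- fit_em(table, spec, settings)
  out <- effect_estimate(fit, "gender=male:exposure")
  attr(out, "fit") <- fit
  out
}

# ---- methods -----------------------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy coefficients of an EM fit
#'
#' @param x An `em_fit`.
#' @param exponentiate Report odds-ratio scale estimates and CI bounds.
#' @param ... Unused.
#' @return A tibble with one row per coefficient of both sub-models
#'   (`model` = `"outcome"` or `"exposure"`).
#' @export
tidy.em_fit <- function(x, exponentiate = FALSE, ...) {
  est <- c(x$beta, x$gamma)
  se <- sqrt(diag(x$covariance))
  out <- tibble::tibble(
    model = rep(c("outcome", "exposure"), c(length(x$beta), length(x$gamma))),
    term = c(names(x$beta), names(x$gamma)),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * stats::pnorm(-abs(unname(est / se))),
    conf.low = unname(est - wald_z_crit * se),
    conf.high = unname(est + wald_z_crit * se)
  )
  if (exponentiate) {
    out <- dplyr::mutate(out,
                         estimate = exp(.data$estimate),
                         conf.low = exp(.data$conf.low),
                         conf.high = exp(.data$conf.high))
  }
  out
}

#' One-row summary of an EM fit
#' @param x An `em_fit`.
#' @param ... Unused.
#' @export
glance.em_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, r = x$settings$r, n = x$n, n_missing = x$n_missing,
    n_dropped = x$n_dropped, n_iter = x$n_iter, converged = x$converged
  )
}

#' Plot the observed-data log-likelihood trajectory of an EM fit
#' @param object An `em_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.em_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$loglik_trajectory) - 1,
                       loglik = object$loglik_trajectory)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "EM iteration", y = "Observed-data log-likelihood",
                  title = sprintf("EM trajectory (r = %g)", object$settings$r))
}

#' @export
print.em_fit <- function(x, ...) {
  cat(sprintf("EM missing-exposure fit (r = %g): n = %d (%d with missing exposure)\n",
              x$settings$r, x$n, x$n_missing))
  cat(sprintf("%s in %d iteration(s); observed-data logLik %.4f\n",
              if (x$converged) "converged" else "NOT converged", x$n_iter, x$loglik))
  eff <- effect_estimate(x, "exposure")
  cat(sprintf("exposure OR %.3f (95%% CI %.3f, %.3f; p = %.3g)\n",
              eff$odds_ratio, eff$ci_low, eff$ci_high, eff$p_value))
  invisible(x)
}
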