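# Numerical core: Newton maximum likelihood for Bernoulli regression with
# per-record non-negative (possibly fractional) weights.  Both EM sub-models
# sit on top of this engine, so it is written defensively: step-halving
# guarantees monotone ascent even with near-degenerate fractional weights.

#' Weighted Bernoulli log-likelihood
#'
#' Evaluates the weighted log-likelihood
#' \eqn{\sum_i w_i [y_i \log \mu_i + (1 - y_i) \log(1 - \mu_i)]} with
#' \eqn{\mu_i = \mathrm{logistic}(x_i^\top \beta)}.  Fitted probabilities are
#' clipped 1e-12 away from the boundary so the value is always finite.
#'
#' @param y Binary response vector.
#' @param design Numeric design matrix, rows aligned with `y`.
#' @param coef Coefficient vector aligned with `design` columns.
#' @param weights Non-negative weights (default all 1).
#' @return The log-likelihood value (finite scalar).
#' @export
bernoulli_loglik <- function(y, design, coef, weights = rep(1, length(y))) {
  design <- as.matrix(design)
  if (length(y) != nrow(design) || length(coef) != ncol(design) ||
      length(weights) != length(y)) {
    stop("dimension mismatch between y, design, coef, weights", call. = FALSE)
  }
  mu <- clip_prob(logistic(drop(design %*% coef)))
  sum(weights * (y * log(mu) + (1 - y) * log(1 - mu)))
}

#' Maximum likelihood for weighted logistic regression
#'
#' Newton-Raphson with step-halving (up to 25 halvings per step) on the
#' weighted Bernoulli log-likelihood.  Convergence requires the gradient
#' sup-norm to fall below `grad_tol`.  Complete separation is reported as an
#' error once any coefficient exceeds 30 in magnitude (the logistic curve is
#' numerically saturated well before that).
#'
#' @param y Binary response vector.
#' @param design Numeric design matrix with named columns.
#' @param weights Non-negative weights, not all zero.
#' @param start Optional starting coefficients (default 0).
#' @param grad_tol Gradient sup-norm at exit.
#' @param max_iter Maximum Newton iterations.
#' @return A list of class `wlogit_fit`: `coefficients`, `covariance`
#'   (inverse weighted Fisher information), `loglik`, `n_iter`, `converged`.
#' @export
fit_weighted_logistic <- function(y, design, weights = rep(1, length(y)),
                                  start = NULL, grad_tol = 1e-8,
                                  max_iter = 100) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (all(weights == 0)) stop("weights must not all be zero", call. = FALSE)
  active <- weights > 0
  qr_act <- qr(design[active, , drop = FALSE] * sqrt(weights[active]))
  if (qr_act$rank < ncol(design)) {
    dropped <- colnames(design)[qr_act$pivot[(qr_act$rank + 1):ncol(design)]]
    stop(sprintf("design is rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  p <- ncol(design)
  coef <- start %||% numeric(p)
  ll <- bernoulli_loglik(y, design, coef, weights)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    mu <- clip_prob(logistic(drop(design %*% coef)))
    grad <- drop(crossprod(design, weights * (y - mu)))
    if (max(abs(grad)) <= grad_tol) {
      converged <- TRUE
      iter <- iter - 1L
      break
    }
    info <- crossprod(design, design * (weights * mu * (1 - mu)))
    step <- solve(info, grad)
    # step-halving: never accept a decrease in the objective
    lambda <- 1
    for (h in seq_len(25)) {
      cand <- coef + lambda * step
      ll_cand <- bernoulli_loglik(y, design, cand, weights)
      if (ll_cand >= ll - 1e-12) break
      lambda <- lambda / 2
    }
    coef <- cand
    ll <- ll_cand
    if (max(abs(coef)) > 30) {
      stop("divergence detected (|coefficient| > 30): data are likely completely separated",
           call. = FALSE)
    }
  }
  if (!converged) {
    mu <- clip_prob(logistic(drop(design %*% coef)))
    grad <- drop(crossprod(design, weights * (y - mu)))
    converged <- max(abs(grad)) <= grad_tol
  }
  mu <- clip_prob(logistic(drop(design %*% coef)))
  info <- crossprod(design, design * (weights * mu * (1 - mu)))
  covariance <- solve(info)
  names(coef) <- colnames(design)
  dimnames(covariance) <- list(colnames(design), colnames(design))
  structure(
    list(coefficients = coef, covariance = covariance,
         loglik = bernoulli_loglik(y, design, coef, weights),
         n_iter = iter, converged = converged),
    class = "wlogit_fit"
  )
}

#' @export
print.wlogit_fit <- function(x, ...) {
  cat(sprintf("Weighted logistic fit: %d coefficient(s), loglik %.4f, %s in %d iteration(s)\n",
              length(x$coefficients), x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(round(x$coefficients, 6))
  invisible(x)
}
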