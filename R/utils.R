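# Internal numerical helpers shared across modules.

logistic <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

# Probabilities entering log-likelihoods are kept this far from {0, 1} so the
# objective stays finite (contract: -Inf is never returned).
.PROB_EPS <- 1e-12

clip_prob <- function(p) pmin(pmax(p, .PROB_EPS), 1 - .PROB_EPS)

# round() uses banker's rounding; printed tables in this field round half up.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

wald_z_crit <- 1.959964
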