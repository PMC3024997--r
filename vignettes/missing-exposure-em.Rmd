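---
title: "EM estimation with a half-missing binary exposure: model, numerics, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EM estimation with a half-missing binary exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The estimation problem

The package targets cohort studies of a rare binary outcome $Y$ (for
example, an autism spectrum diagnosis during follow-up) and a binary
exposure $X$ (fetal hypoxia at birth, ascertained by blood-pH tests) that
was measured in only a fraction of subjects — in perinatal registries,
roughly half of births. Measured covariates split into two vectors with
different causal roles: $Z$, categorical maternal and obstetric
characteristics assumed to act on the outcome only through the exposure
(maternal age and anthropometry, diabetes, bleeding, smoking, parity,
pre-eclampsia, presentation, labor type, gestational age, birth weight,
Apgar), and $W$, confounders of the exposure–outcome relation (birth-year,
socio-economic class, and gender unless gender is under study as an effect
modifier).

Two logistic models are estimated jointly by maximum likelihood:

$$
\operatorname{logit} P(Y=1 \mid X, W) = \beta_0 + \beta_X X + \beta_W' W,
\qquad
\operatorname{logit} P(X=1 \mid Z) = \gamma' Z .
$$

A subject with observed exposure contributes
$f(Y \mid X, W; \beta)\, P(X \mid Z; \gamma)$. A subject with missing
exposure contributes the mixture

$$
f(Y \mid 1, W; \beta)\, p_1 + f(Y \mid 0, W; \beta)\,(1 - p_1),
\qquad
p_1 = r\,\pi(Z), \quad \pi(Z) = \operatorname{logit}^{-1}(\gamma' Z),
$$

where $r \in [0,1]$ is a fixed **sensitivity ratio**: the ratio of the
covariate-conditional exposure probability in the untested group to that in
the tested group. $r = 1$ states that, given $Z$, the untested are as likely
exposed as the tested — missingness at random. $r < 1$ encodes the clinical
reality that testing is ordered on suspicion: untested children are *less*
likely hypoxic than tested children with identical records. $r$ is not
identifiable from the data and is therefore supplied by the analyst and
swept over a grid (`r_sweep()`, default $\{0.1, 0.2, 0.5, 0.7, 1.0\}$,
tagged strong/moderate/weak deviation from MAR).

### Why this factorization

The description "model $X$ using $Z$s and $Y$" admits two readings: a
directly parameterized regression of $X$ on $(Z, Y)$, or a generative
factorization $P(Y \mid X, W)\,P(X \mid Z)$ whose Bayes posterior for a
missing $X$ automatically involves $Y$ through the outcome likelihood — and
hence contains the parameters of interest. The package implements the
factorization reading: it yields a genuine EM for a well-defined
observed-data likelihood (so monotone ascent and oracle equivalence are
testable properties rather than hopes), and the posterior weight

$$
w_i = \frac{p_{1i} f(Y_i \mid 1, W_i)}{p_{1i} f(Y_i \mid 1, W_i) +
      (1 - p_{1i}) f(Y_i \mid 0, W_i)}
$$

is exactly "weighing the two possibilities of the missing value". The
direct-regression reading has no such likelihood interpretation once $r$
enters, and is not implemented.

Likewise, $r$ acts on the *probability* scale, $p_1 = r\pi(Z)$, matching
its definition as a ratio of probabilities; an odds-scale tilt was
considered and rejected because it would no longer mean what the ratio is
defined to mean. For $r \le 1$, $p_1 \le \pi < 1$ always, so the prior is
well defined.

## The algorithm

1. **Initialization** — complete-case fits of both models on the tested
   subjects. Cheap and consistent under MAR; under the NMAR tilt it is only
   a starting point, and the EM moves away from it.
2. **E step** — posterior weights $w_i$ for every missing-exposure record.
3. **M step** —
   * $\beta$: weighted logistic regression on the pseudo-record expansion
     (observed records with weight 1; each missing record entered twice,
     as $X = 1$ with weight $w_i$ and $X = 0$ with weight $1 - w_i$);
   * $\gamma$: Newton maximization of the tilted objective
     $Q(\gamma) = \sum_{\text{obs}} [X \log \pi + (1-X)\log(1-\pi)]
     + \sum_{\text{miss}} [w \log(r\pi) + (1-w)\log(1 - r\pi)]$.
     At $r = 1$ this reduces exactly to a weighted logistic fit on the same
     pseudo-records (a regression-tested identity); at $r < 1$ the
     $\log(1 - r\pi)$ term requires the bespoke Newton step.
4. **Convergence** — sup-norm change of $(\beta, \gamma)$ below `tol`
   (default $10^{-6}$), or `max_iter` (default 500, twice the iteration
   budget reported adequate for cohorts of this type); non-convergence is
   flagged, never silently returned. The observed-data log-likelihood is
   recorded every iteration and is nondecreasing — this is asserted in the
   test suite at a relative tolerance of $10^{-8}$ on every shipped fit.

### Variance estimation

The default is the observed information: a central-difference Hessian of
the observed-data log-likelihood at the optimum, step
$10^{-4}(1 + |\theta_j|)$ per coordinate, negated and inverted. A
nonparametric bootstrap (resample subjects, re-run the EM; default 200
replicates, seeded) is provided as a cross-check because the two can
disagree under near-boundary weights. With no missing data the
observed-information covariance reproduces the standard logistic-regression
covariance blockwise, which the tests assert at $10^{-4}$.

Wald intervals use the two-sided critical value 1.959964 throughout. In
gender-stratified analyses the exposure model is refitted within each
stratum, so the $Z$-to-$X$ relation is allowed to differ by gender.

## Numerical choices

* **Weighted logistic core** — Newton–Raphson with step-halving (up to 25
  halvings; a step is accepted only if the objective does not decrease).
  Plain IRLS can overshoot when near-degenerate fractional weights make the
  information matrix ill-scaled; halving makes ascent unconditional.
  Gradient sup-norm at exit $\le 10^{-8}$.
* **Separation** — any coefficient exceeding 30 in magnitude aborts with a
  complete-separation error: the logistic curve is numerically saturated
  far below that, so further growth is divergence, not information.
* **Rank deficiency** — detected by pivoted QR on the weighted design; the
  error names the collinear columns.
* **Probability clipping** — fitted probabilities are kept $10^{-12}$ away
  from 0 and 1 inside logs, so log-likelihoods are finite by contract.
* **Tilted Newton** — the $Q(\gamma)$ Hessian is not globally negative
  definite for $r < 1$ (the $\log(1-r\pi)$ term convexifies where $\pi$ is
  large); a ridge is added escalatingly if factorization fails or the step
  is not an ascent direction, and step-halving guards the objective.
* **NMAR rate solver** — `solve_missingness_rates()` inverts the ratio
  $r(a, b, \pi)$ for $a = P(\text{miss} \mid X=1)$ by vectorized bisection
  (80 halvings, bracket $(0, b]$, accuracy far below $10^{-10}$); the outer
  calibration of $b$ to the target overall missingness rate is a
  `uniroot()` on the realized $\pi_i$.
* **Rounding** — printed-table reproductions round half-up (2 decimals for
  outcome-rate tables, integers for ascertainment tables), matching the
  convention of published tables; `round()`'s banker's rounding does not.
* **Reference categories** — always the first category listed in the
  schema; deterministic and visible in the schema file rather than locale-
  or data-dependent.
* **Records with absent covariates** — excluded from model fitting with a
  reported count (complete-case in $Z$/$W$); absent gestational-age flags
  exclude a child only from full-term subsets, never from all-ages
  analyses.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the estimator
assumes, with known truth retained (`truth_x`, `missing_indicator`):

* categorical covariates drawn independently; the default configuration has
  eight exposure drivers (maternal age, parity, smoking, diabetes,
  pre-eclampsia, labor type, presentation, birth-weight class) with
  prevalences loosely matching obstetric frequencies, and two confounders
  (birth-year 1998–2004 uniform; socio-economic class low/mid/high);
* exposure from $\operatorname{logit}^{-1}(\gamma' Z)$, marginal prevalence
  calibrated to 14% — the positivity rate among tested births in the
  emulated setting — by exact enumeration of the covariate joint
  distribution (covariate independence makes the joint enumerable, so the
  intercept solves the target exactly rather than by simulation);
* outcome from $\operatorname{logit}^{-1}(\beta' (X, W, \text{gender}))$,
  overall prevalence calibrated to 0.52% with a male:female odds ratio of
  5, matching the strong male excess of the emulated outcome; the default
  true exposure odds ratio is 1.5;
* missingness: `mcar` (uniform), `mar` (logistic in chosen $Z$ terms and
  optionally the outcome, intercept solved in-sample for the target rate;
  default rate 0.517, the untested fraction seen in practice), or `nmar`
  (per-subject probabilities $(a_i, b)$ with $a_i$ solved from the target
  ratio $r$ given $\pi_i$ — so the covariate-conditional ratio equals the
  target *by construction* — and $b$ calibrated to the overall rate).

`empirical_r()` is the validation counterpart: the ratio of true-exposure
prevalence in the missing versus the observed group, either marginal or
within covariate strata (size-weighted). The stratified version is the one
that matches the conditional definition of $r$; the marginal version can
differ slightly when $\pi(Z)$ varies (a Jensen effect), which is why the
self-consistency tests stratify.

### What the generator does not emulate

Raw pH values and test-combination choice, follow-up and censoring, the
joint dependence structure of real obstetric covariates (drawn
independently here), gestation as a process (the full-term flag is an
independent Bernoulli kept for subset operations), and — importantly —
missingness that depends on the outcome *beyond* the exposure given $Z$.
The NMAR mechanism depends on $X$ only. Passing recovery tests therefore
demonstrates correctness of the estimator under its stated assumptions, not
robustness to the richer selection processes real registries may harbor.

### A caution on sensitivity-sweep profiles

On a fixed dataset the exposure odds ratio as a function of the analysis
$r$ is typically gentle: conditional on $Z$, cases and non-cases with
missing exposure receive the same prior, so the fractional table they
contribute is largely self-consistent with the current fit, and the
systematic movement with $r$ is second-order relative to sampling noise at
realistic cohort sizes with a rare outcome. Sweep profiles need not be
monotone in $r$ on a given cohort, and `r_sweep()` deliberately reports a
non-monotone profile as a warning (it can also indicate non-convergence)
rather than an error. Large monotone shifts across $r$ — as seen in
registry analyses where untested children show depressed outcome rates not
explained by covariates — are a feature of such data, not a mathematical
guarantee of the estimator. The matched-$r$ analysis is, however, the least
biased one, which the recovery experiments probe.

## Experiment sizes used by the test suite

The shipped tests fix their problem sizes as a design choice balancing
Monte-Carlo resolution against a single-core run: oracle-equivalence
comparisons (EM versus quasi-Newton maximization of the observed-data
likelihood from a cold start) use ten instances of ≤ 500 records at
$r \in \{0.1, 0.5, 1\}$ with agreement to $10^{-4}$; bias recovery uses 25
cohorts of $n = 20{,}000$; CI coverage uses 100 cohorts of $n = 10{,}000$
with the acceptance band $[89\%, 99\%]$; generator self-checks run at
$n = 50{,}000$ (pooled to $200{,}000$ for rate targets). Recovery
experiments use a compact two-covariate/one-confounder configuration
(about ten free parameters) rather than the rich default: with ~50–100
outcome events per cohort, a lean parameterization keeps the weighted
likelihoods well conditioned and the runs fast, while exercising exactly
the same code paths.

## Known limitations

* $r$ is assumed common across subjects and fixed by the analyst; no prior
  on $r$ or estimation of $r$ is attempted (not identifiable here).
* Wald intervals with very sparse outcomes ($\lesssim 50$ events) can be
  erratic; a small fraction of tiny-cohort replicates fail by separation
  and are excluded with a reported count.
* Exposure must be binary and models logistic; no regularization, robust
  variance, or clustering.
* Under the NMAR mechanism the tested-group exposure probability is not
  exactly logistic in $Z$ (mild model misspecification by construction);
  its effect on the exposure coefficient is negligible at the studied
  scales but is worth remembering at extreme missingness rates.
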