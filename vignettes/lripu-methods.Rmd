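---
title: "Hybrid product-unit logistic regression for graft-survival prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid product-unit logistic regression for graft-survival prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lripu)
```

## The modelling problem

Donor-recipient allocation in lung transplantation needs a calibrated
estimate of how likely a particular donor-recipient pairing is to result in
a graft that survives the first six months. The predictors are a mix of
recipient characteristics (age, sex, underlying disease, pre-transplant
status, spirometry), donor characteristics (age, sex, cause of death,
ventilation time, oxygenation index) and operative factors (transplant
type, cold ischemia class, bypass, tailoring). After one-of-k expansion of
the five categorical variables this gives 36 encoded covariates
`x1`...`x36` and a binary endpoint `y` (graft alive at six months).

Plain logistic regression (LR) over these covariates is interpretable but
purely additive on the log-odds scale. This package implements a hybrid:
a *product-unit neural network* (PUNN) supplies a small number of
multiplicative basis functions

$$B_k(x) = \prod_i x_i^{w_{ki}}, \qquad w_{ki} \in \mathbb{R},$$

whose architecture (which covariates enter which unit) and exponents are
found by an evolutionary algorithm (EPUNN); the final classifier — LR with
initial covariates and product units, LRIPU — is a maximum-likelihood
logistic regression over the 36 covariates *plus* the evolved units with
their exponents frozen:

$$\ln\frac{p}{1-p} = \beta_0 + \sum_{j=1}^{36}\beta_j x_j +
  \sum_k c_k \prod_i x_i^{w_{ki}}.$$

A product unit with real exponents expresses high-order interactions and
ratios (e.g. an age-to-oxygenation trade-off) with very few parameters, and
the fitted model remains small enough to read coefficient by coefficient.

## Covariate encoding and scaling

**One-of-k dummies.** Every categorical variable is expanded into one
indicator per category with no reference level dropped, because the
published form of the model carries a coefficient for every dummy. The
price is exact collinearity: each dummy group sums to the intercept column.
The logistic fit therefore always carries a small ridge penalty (below).

**The [1, 2] range.** All 36 columns, binaries included (0 → 1, 1 → 2), are
mapped affinely by `x' = 1 + (x - min)/(max - min)` with per-column
training min/max. Strict positivity is not cosmetic: a non-integer power of
a non-positive base is undefined, and a zero-valued covariate would
otherwise annihilate an entire product unit. The training min/max are
stored in every fitted model; prediction-time values outside the training
range are clipped back into [1, 2] with a warning, again to protect the
powers. A constant column is mapped to all-1 — the multiplicative identity
— with a warning, since it carries no information either way.

**Missing data.** The default policy is complete-case removal;
median (continuous) / mode (categorical) imputation is available behind
`encode_records(na_action = "impute")`. Nothing in the published analysis
pins down the original policy, so the default is the conservative one.

## The evolutionary search (EPUNN)

The search is mutation-only evolutionary programming — crossover on
product units tends to recombine incompatible exponent patterns, and the
lineage of methods this follows is mutation-driven. Per generation:

* **Selection.** Linear rank-based selection (pressure 1.5 by default)
  over a population of 100; elitism copies the single best individual
  unchanged, which makes the best-fitness trace non-decreasing by
  construction.
* **Structural mutation** (probability 0.5 per offspring) applies exactly
  one of four moves, renormalised over the feasible ones: add a unit
  (up to `max_units`, default 3), delete a unit, add a connection (a new
  nonzero exponent), delete a connection (a unit losing its last
  connection is removed). Exponents are stored sparsely so each move is
  O(1).
* **Parametric mutation** perturbs parameters with Gaussian noise. Three
  details matter in practice, all adopted after watching the search lock
  into wrong-sign exponent basins on recovery tasks: each parameter is
  perturbed independently with probability 1/2 (so good partial solutions
  are not destroyed wholesale); each offspring draws a severity multiplier
  from {0.01, 0.1, 1, 10} (mostly gentle fine-tuning, occasionally a kick
  big enough to cross a sign change); and the scale is annealed by parent
  fitness, so strong individuals receive gentler noise. A global
  temperature adapts by the 1/5-success rule on parametric-only offspring.
* **Fitness** is `1/(1 + CE)` where CE is the mean cross-entropy of the
  network's logistic output — bounded in (0, 1], higher is better, and an
  individual whose logit overflows scores 0 instead of crashing the run.

Initial individuals carry 1 to `max_units` units, each with 1-3
connections to uniformly chosen covariates, exponents uniform on [-2, 2]
and standard-normal coefficients. Exponent magnitudes are clipped at 10
(the largest published exponent is about 6, so the bound is loose).
No published EA hyperparameters exist for this model family; every value
above is a package default exposed through `ea_config()`, not a claim
about how the published model was obtained.

All randomness flows through R's global RNG from `config$seed`: identical
data, config and seed give bit-identical traces.

## The hybrid fit (LRIPU)

`fit_lripu()` builds the feature matrix `[1, X, B]` (36 scaled covariates
plus one column per frozen product unit) and maximises the ridge-penalized
binomial likelihood by iteratively reweighted least squares. The exponents
are *not* refit — refitting them would restate the evolutionary search;
only the linear coefficients and the units' output coefficients move.

Numerical choices:

* **Ridge.** Default `1e-6` on all non-intercept coefficients. This exists
  because the one-of-k dummy blocks are exactly collinear; the penalty
  selects the minimum-norm representative of each equivalence class. On
  divergence (typically quasi-complete separation) the ridge escalates
  tenfold up to `1e-2`, and the escalation is reported in the fit report;
  a fit that still diverges errors out with a diagnostic.
* **Convergence.** Maximum absolute coefficient change below `1e-8`, or at
  most 100 iterations. A second criterion accepts a maximum absolute
  penalized score below `1e-10` together with a small step: with condition
  numbers around 1e10 (the collinear dummies again) the coefficient update
  wiggles at rounding level along null directions even when the gradient
  has vanished. Running out of iterations without meeting either criterion
  is treated as divergence and triggers the ridge escalation, because
  under separation the score also vanishes while the coefficients drift
  outward.
* **Standard errors** come from the inverse *penalized* Fisher information
  `(X'WX + λI)^{-1}`. In identifiable directions (λ tiny relative to the
  information) these are ordinary Wald SEs; along the dummy null
  directions they are enormous, which is the honest statement that the
  data do not identify those contrasts.

**Model selection across EA runs.** `train_lripu()` runs the evolutionary
search `n_runs = 5` times (seeds `seed + 0:4`), every run on the full
training data, and scores each candidate basis by stratified 4-fold
cross-validated cross-entropy of the hybrid fit; the winning basis is
refit on all training data. The candidate set always includes the empty
basis, so when no evolved unit survives cross-validation the hybrid backs
off to plain logistic regression instead of carrying a hallucinated
interaction. An earlier protocol held back a single validation quarter,
but on cohort-sized data (~300 training records) starving the search of a
quarter of the rows cost more than the cleaner validation bought.

**Train/test protocol.** Stratified 75/25 splits with seeded shuffling,
preserving the class ratio to the nearest record. No canonical protocol accompanies the published model; this one is
fixed here so every comparison is reproducible.

## The synthetic cohort generator

Real transplant records are not available to this package, so every
pipeline stage is exercised on synthetic cohorts with known ground truth
(`simulate_cohort()`):

* **Marginals** (`default_marginals()`) are invented but clinically
  plausible: categorical probabilities for disease, pre-transplant status,
  cause of death, transplant type and ischemia class; Bernoulli rates for
  the binaries; truncated normals for ages (years), intubation time
  (days), oxygenation index, pressures (mmHg) and spirometry (% predicted).
  Covariates are independent by default; an exchangeable Gaussian copula
  (`correlation`) can couple the continuous block. No claim is made that
  these match any real cohort's marginals — none are published for the
  clinical setting this emulates.
* **Ground truth** (`default_truth_model()`) is an LRIPU-form model in the
  scaled space: one product unit on recipient age, donor oxygenation and
  pre-transplant FVC with exponents (2, -2, 1.5) and output coefficient
  -1.6 — a deliberately strong three-way interaction, small enough for the
  EA to recover at desk scale — plus six nonzero linear coefficients with
  clinically sensible signs. The intercept (3.60) was calibrated once, by
  root-finding on a 200 000-record sample, so the marginal survival rate is
  0.70; no six-month survival rate is published for this
  setting, so 0.70 is a placeholder, not a study value. `default_linear_truth_model()` is the
  same model without the product unit (intercept recalibrated to 0.54) and
  serves as the no-interaction control condition.
* **Outcomes** are Bernoulli draws from the true probabilities, which are
  stored alongside the records; regeneration from the same spec is
  bit-identical.

What passing on these cohorts does and does not show: recovery and
comparison results demonstrate that the estimator and search behave
correctly when the model family contains the truth and covariates are
(near-)independent. Real registry data have correlated covariates,
informative missingness, measurement drift over 23 years of practice and
model misspecification; nothing here certifies behaviour under those.

## Study sizes used in the checks

The packaged checks run, at fixed seeds: coefficient recovery on 100
cohorts of n = 5000 (each linear coefficient within 3 SE of truth in at
least 95% of replicates); evolutionary recovery of a single known product
unit (`x1^2 x2^-1`, n = 1000 training records, population 200, 300
generations, test cross-entropy within 0.05 of the generator's); and the
LR-versus-LRIPU comparison on 20 replicate cohorts of n = 404 under both
the interaction-bearing and the pure-linear truth (3 EA runs per
replicate in these experiments — the selection gain of further runs is
noise-level at this n and the runtime doubles). At these sizes the
comparison margin is intrinsically thin: even fitting the *true* basis
lifts held-out CCR by only about 0.014 over LR (Bayes CCR ≈ 0.77 vs LR
≈ 0.73), so the expected evolved-basis gain is a few thousandths. The
checks assert the direction of the mean gain, not a large effect, and
assert *no significant* gain under the pure-linear truth — the hybrid
must not hallucinate interactions.

## The printed-model tools

`parse_model_expression()` reads the `ln(p/(1-p)) = ...` dialect used to
publish models of this form, including the quirks of text extracted from
journal pages: caret-delimited superscripts (`(x_9_)^2.27^`), Unicode
minus signs, stray carets inside factor parentheses and redundant closing
parentheses. Parsed models remember their numeric literals, so
`print_model_expression()` reproduces them character for character; for
fitted models it prints at 17 significant digits, which makes
print-then-parse an exact round trip. The bundled fixture
(`published_model()`) has 48 parameters — intercept, 36 linear
coefficients, one product-unit coefficient and 10 exponents — and its
coefficient report reproduces the published extremes (strongest positive
linear coefficient 23.50 on pre-transplant FVC; strongest negative -23.51
on pre-transplant FEV1; largest exponent 6.03 on the bilobular-cadaver
dummy).

One reinterpretation is deliberate: the published interpretation speaks of
probabilities "when the rest equaled zero", but zero is unattainable after
[1, 2] scaling. `covariate_effect_curve()` therefore sweeps one covariate
across [1, 2] at a user-chosen baseline, defaulting to all-ones — the
scaled minimum — and the report states directions only as computed from
the model.

## Known limitations

* The EA is a stochastic global search; at the packaged budgets it
  reliably recovers a single planted unit, but nothing guarantees the
  global optimum on richer landscapes, and the comparison gain on
  cohort-sized data is small (see above).
* Within-dummy-group contrasts are not identifiable under one-of-k coding;
  individual dummy coefficients are reported as the ridge's minimum-norm
  representatives and should be read jointly, not singly.
* The binary six-month endpoint is modelled as stated; no time-to-event
  structure, no multiclass extension, no external validation.
* Prediction-time clipping to the training range means extrapolation
  beyond observed covariate ranges is deliberately flat.
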