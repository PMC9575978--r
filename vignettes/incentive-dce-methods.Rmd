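---
title: "Designing and analysing a financial-incentive smoking-cessation DCE"
author: "incentdce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing a financial-incentive smoking-cessation DCE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incentdce)
```

## The problem

Financial-incentive (FI) programs reward smokers for verified abstinence.
Which program designs smokers would actually enrol in — and how enrolment
responds to the incentive amount — can be studied with a discrete choice
experiment (DCE): respondents repeatedly choose between two hypothetical
programs described by five attributes (total incentive amount in pounds,
cash vs voucher rewards, consistent vs escalating reward schedule, session
frequency, healthcare vs workplace location), then state whether they would
enrol in their preferred program at all. `incentdce` implements the whole
workflow: design construction, cohort simulation, data cleaning, panel
mixed logit estimation, and post-estimation economics.

## The model

Respondent $i$ facing task $t$ chooses among program A, program B and an
opt-out ("would not enrol"). Utilities are

$$
V_{ijt} = \alpha_i \, a_{jt}/u + \beta_i' x_{jt}, \qquad
V_{i0t} = \delta_i,
$$

where $a_{jt}$ is the amount (rescaled by the unit $u$, default £10),
$x_{jt}$ the effects-coded categorical attributes, and the opt-out carries
only an alternative-specific constant (ASC). With i.i.d. extreme-value
errors the choice probabilities are the softmax of the three utilities.
Preference heterogeneity enters through independent normal random
coefficients $\beta_{ik} \sim N(b_k, w_k^2)$ on the categorical attributes;
the amount coefficient and the ASC are fixed apart from income-group shifts
($\alpha_i = \alpha + \gamma^{a}_{g(i)}$, $\delta_i = \delta +
\gamma^{\delta}_{g(i)}$, low income the reference). Effects coding makes
each attribute's level effects sum to zero, so the omitted level's estimate
is minus the sum of the others and program utilities are expressed relative
to the "average" program — which is what makes the ASC interpretable as the
utility of not enrolling in an average program.

The panel mixed logit likelihood integrates over the random coefficients
for each respondent's whole block of ten tasks:

$$
L_i = \int \prod_t P_{it}(\beta)\, \phi(\beta; b, w)\, d\beta
\approx \frac{1}{R} \sum_{r=1}^{R} \prod_t P_{it}(\beta_{ir}),
$$

with $\beta_{irk} = b_k + w_k \Phi^{-1}(u_{irk})$ evaluated at Halton
points $u$. Maximum simulated likelihood estimation uses BFGS with the
analytic gradient, warm-started at the conditional-logit estimates with
SDs initialized at 0.1; standard errors come from the inverse numerical
Hessian. The SDs are identified only up to sign and are reported as
absolute values.

## Design construction

The design module builds paired choice sets that are efficient under the
*utility-neutral* (null-prior) criterion: with all coefficients at zero,
the paired-set information matrix is $M = \tfrac14 \sum_s z_s z_s'$ with
$z_s$ the difference of the coded alternatives, and the D-error is
$\det(M^{-1})^{1/p}$. A coordinate-exchange search (default 20 restarts)
minimizes the D-error, rejecting sets whose alternatives are identical or
where one alternative strictly dominates the other under asserted
preference directions.

Two design decisions deserve comment:

* **Level balance is a constraint, not only a diagnostic.** With the
  amount coded linearly, unconstrained D-optimality assigns it only its
  extreme levels (£50/£1,000). That makes most choices nearly
  deterministic and leaves the amount-by-income interactions essentially
  unidentified — a separation-like flat likelihood. The search therefore
  starts from level-balanced random designs and rejects exchanges that
  push any attribute's level-count spread beyond a cap (default 2),
  mirroring the level-balance check that such designs are conventionally
  screened with. The linear amount coding is retained inside the
  information matrix.
* **Blocking** is a greedy assignment of sets to equal blocks minimizing
  per-block level-count imbalance (ties by set order). Respondents are
  stratified so that income-by-block counts differ by at most one.

The dominance-check set pits the best level of every attribute against the
worst, per directions that must be asserted by the analyst (they are part
of the catalog, not estimated). Overlap is reported as a per-attribute
rate and warned about above 0.5, not enforced.

## What the synthetic cohorts emulate — and what they do not

`simulate_cohort()` draws each respondent's coefficients from the
population model above and answers every task by sampling the
three-alternative logit (softmax sampling by default; Gumbel-max sampling
is also implemented and is distributionally identical). The two-stage
response (preferred program, then enrol yes/no) is generated from the
single three-alternative choice: if the opt-out is drawn, the reported
preference is the higher-utility program and enrolment is "no". A truly
sequential decision process is *not* modelled. The default
`true_preferences()` are the published point magnitudes (e.g. cash mean
0.331, SD 0.416; amount 0.046 per £10; ASC 1.102), so recovery tests
target realistic effect sizes; the default cohort is 460 completers
(150/155/155 by income) with 3 nontraders, 15 dominance failers and 12
universal opt-outs planted.

Planted counts are exact by construction: a model-driven respondent who
would by chance trip a cleaning rule (a constant preferred position, or
refusing every program) receives a minimal deterministic repair — one
preference flipped on their most utility-balanced task, or one enrolment
granted on their most enrolment-favourable task. This touches on the
order of one task in several thousand. The alternative of resampling the
whole respondent was rejected because truncating entire response vectors
conditions the joint distribution and measurably manufactures preference
heterogeneity that the generating process does not contain.
Real features the generator does not emulate: response times, item
nonresponse, fatigue or learning across tasks, correlated random
coefficients, and any systematic behaviour of real inattentive responders
beyond the three planted archetypes. Passing recovery tests therefore
demonstrates internal consistency of the estimator under the model's own
assumptions, not robustness to misspecification.

## Cleaning and encoding conventions

The exclusion cascade runs in a fixed order — nontraders (constant
position, extended symmetrically to always-B), dominance-check failures,
universal opt-outs — each rule applied to the survivors of the previous,
and each removal attributed to the first rule that caught it. Descriptive
enrolment statistics are computed *after* the dominance exclusion but
*before* removing universal opt-outs, the only convention under which
"always enrol" and "never enrol" percentages share one denominator.
Display rounding is half-up, two decimals.

Encoding produces three rows per respondent-task. Program rows carry the
rescaled (uncentered) amount, effects-coded attributes and
amount-by-income columns; the opt-out row carries the ASC and its income
interactions with all attribute columns zero. The rescale unit defaults to
£10, consistent with published WTA magnitudes being roughly ten times the
coefficient ratios.

## Numerical choices

* Halton draws: one prime base per random term in column order, first 100
  points discarded, 500 draws per respondent by default (200 in the
  bundled study-scale configuration; at 200 draws the simulation noise is
  already well below sampling noise at these sample sizes).
* Simulated likelihood: per-respondent task products in log space with
  max-subtraction; draw averaging by log-sum-exp. The degenerate case
  $w = 0$ reproduces the closed-form conditional logit to $10^{-10}$,
  which the test suite uses as a cross-implementation oracle (the
  conditional logit is implemented independently in R; the simulated
  likelihood in C++).
* Optimizer: BFGS, relative tolerance $10^{-10}$, iteration cap 500;
  convergence additionally requires the gradient max-norm below
  $10^{-2} \cdot \max(1, |\ell|)$ — at a boundary optimum of a simulated
  likelihood the absolute gradient norm does not vanish, so the scaled
  criterion is the meaningful one. Ties in the preferred-program report go
  to position A.
* Krinsky–Robb intervals: 10,000 multivariate-normal parameter draws,
  percentile bounds (not bias-corrected). WTA interval endpoints are also
  reported in presentation order (closer to zero first), the convention
  for negative WTA ranges.
* Uptake predictions integrate over the random coefficients by simulation
  (2,000 draws, seeded) or evaluate at the means (`means_only = TRUE`).
  The means-only mode is the one whose curve is exactly logistic, hence
  strictly increasing in amount when the amount coefficient is positive
  and concave above probability one half. The cash-versus-voucher uptake
  gap is guaranteed to shrink with the amount only where *both*
  configurations enrol a majority: below one half the logistic density is
  still rising, and the gap can widen. Tests assert the shrinking gap on
  that region.

## Problem sizes used by the test suite

Unit tests run on cohorts of 12–60 respondents. The study-scale checks
use the 460-completer fixture for cleaning and encoding, a 501-respondent
cohort for the degenerate-mixture oracle, and a 2,000-respondent cohort
with 200 Halton draws for parameter recovery (all means within three
standard errors of the generating values; the well-identified SDs — cash
and healthcare — likewise). Krinsky–Robb calibration uses 1,000
replications of 10,000 draws. These sizes were chosen so the whole suite
exercises every stage at magnitudes where asymptotic behaviour is visible.

## Known limitations

* Random coefficients are independent (diagonal covariance); correlated
  tastes are not estimable here.
* Only normal mixing is implemented — no lognormal or triangular
  distributions, no latent classes, no WTP-space parameterization, no
  Bayesian estimation.
* Designs are paired (two alternatives plus opt-out); partial profiles
  and larger sets are out of scope.
* The indifference amount and WTA ratios are mean-coefficient quantities;
  with heterogeneity, individual indifference amounts vary around them.
* Real-data coefficient reproduction requires the original deposited
  dataset, which this package deliberately does not fetch; all empirical
  statements in the documentation are about synthetic cohorts generated
  by the package itself.
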