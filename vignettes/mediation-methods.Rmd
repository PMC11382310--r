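---
title: "Methods: survival mediation with a binary mediator, propensity matching, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survival mediation with a binary mediator, propensity matching, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rilmed)
```

## The estimand and the model

The package asks a mediation question about a two-arm observational cohort:
for exposure $A$ (1 = proton beam therapy, 0 = photon IMRT), binary mediator
$M$ (grade 4 radiation-induced lymphopenia during chemoradiation), and
right-censored overall survival $T$, how does the total effect of $A$ on $T$
split into a natural direct effect (NDE: switch the modality but hold each
patient's mediator at its photon-world distribution) and a natural indirect
effect (NIE: hold the modality and let only the mediator distribution shift)?

Two parametric models carry the analysis, both fit on the propensity-matched
cohort and adjusted for the propensity score as a covariate:

* a logistic model for the mediator, $\mathrm{logit}\,P(M=1|A,C) =
  \beta_0+\beta_1 A+\beta_2'C$;
* an accelerated failure time model for survival with Weibull shape fixed at
  1 — i.e. an exponential model, linear in log time:
  $\log T = \theta_0+\theta_1 A+\theta_2 M+\theta_3 AM+\theta_4'C+\varepsilon$.

Because $M$ is Bernoulli given $(A, C)$, the counterfactual expectation
$E[T(x, M(x'))\,|\,c]$ is a two-point sum, and the effects have closed forms
(see `?natural_effects`). `rilmed` implements those closed forms directly and
the test suite verifies them, on random parameter draws, against (a) the
two-point summation computed independently and (b) Monte-Carlo simulation of
the counterfactuals — the closed form is never trusted on its own authority.
Three consequences of the model are worth keeping in mind:

* With shape 1, a log time-ratio is minus a log hazard ratio, so effects are
  reported on both scales and $HR_{TE} = HR_{NDE}\cdot HR_{NIE}$ holds to
  machine precision (it is an algebraic identity, not an approximation).
* Outcome-model covariates cancel from all three ratios; only the mediator
  model's covariates enter, through the conditioning values `c_cond`.
* The identification requires the usual sequential-ignorability assumptions
  (no unmeasured exposure-outcome, exposure-mediator, or mediator-outcome
  confounding given $C$, and no mediator-outcome confounder affected by the
  exposure). Nothing in the fitting can detect violations; the propensity
  machinery only addresses the measured-confounder part.

## Confidence intervals, PM, and the median conversion

The default intervals are delta-method: the gradient of each log effect with
respect to the stacked $(\beta,\theta)$ is taken by central differences with
step $10^{-6}\max(1,|\text{param}|)$, and the joint covariance is block
diagonal because the two likelihoods share no parameters. A percentile
bootstrap (`ci_method = "bootstrap"`) is provided for small strata; it
resamples whole matched pairs when a `pair_id` column is present, otherwise
rows, and is seeded through the same substream scheme as everything else.

The proportion mediated is computed on the excess-relative-hazard scale,
$PM = e^{NDE}(e^{NIE}-1)/(e^{NDE+NIE}-1)$ with log-HR arguments. This formula
is only interpretable as a proportion when the total-effect HR is below 1 and
both effects point the same way, so `rilmed` reports it unclamped together
with a validity flag rather than truncating to $[0,1]$.

The indirect effect is also expressed in months: the reference (photon) arm's
hazard $\lambda$ is estimated by an intercept-only exponential fit on that arm
(so $\hat\lambda = \text{events}/\text{total follow-up}$), the hazard is
scaled by $HR_{NIE}$, and exponential medians are differenced:
$\Delta = (\ln 2/\lambda)(1/HR_{NIE}-1)$, with interval endpoints obtained by
substituting the NIE interval endpoints. A "marginal" hazard could also be
defined as the covariate-adjusted fit evaluated at the covariate means; the
intercept-only definition was chosen because it is the estimand a clinician
reading a single-arm median would expect, and because the adjusted variant
differs only in second-order terms at the conditioning point. Note the
implied median is $\ln 2 \cdot \hat{E}[T]$, which differs from the
Kaplan-Meier median whenever the arm's survival is not exponential — the two
summaries answer slightly different questions and both are reported by the
pipeline.

## Propensity model and optimal matching

Screening fits one logistic (exposure) and one Cox (survival) model per
candidate covariate and flags anything significant for either endpoint at
`alpha = 0.05`. The propensity model then starts from all candidates and
removes, one at a time, the non-forced term with the largest term-level Wald
p while that p exceeds 0.05, refitting after each removal; age and surgical
status are forced. The removal criterion is a genuinely open choice — the
clinical literature's convention is p-based backward elimination, but AIC is
offered (`criterion = "aic"`) because p-thresholding is known to be
anti-conservative for prediction purposes. Note one behavior users of
p-based stepwise should expect: under a complete null, the last surviving
candidate is min-p biased, so with $k$ null candidates roughly
$1-(1-\alpha)^k$ of runs retain at least one of them. The tests assert this
calibrated behavior rather than an idealized zero-retention.

Matching is 1:1 without replacement, minimizing the **total** absolute
distance between paired scores — the global assignment optimum, not greedy
nearest-neighbour. Because the distance is an absolute difference on a line,
an optimal matching can be taken non-crossing in the score order (a standard
exchange argument), which reduces the assignment problem to an
$O(n\,m)$ dynamic program over the sorted arms. The tests verify global
optimality against exhaustive enumeration of all pairings on small instances
and confirm the solution never exceeds greedy matching on large ones.
Distances are logit-scale by default (score distances near 0/1 are otherwise
compressed); probability scale is available, and an optional caliper drops
wide pairs after the optimum is found. Ties are broken by lowest patient id,
making the matching invariant to row order.

## The synthetic cohort generator

The patient-level data behind the motivating analysis are not deposited, so
the generator is a first-class module: it draws cohorts with exactly the
statistical structure the inference assumes — confounded exposure assignment
(logistic in the covariates), a logistic binary mediator, an exponential AFT
outcome, and independent administrative censoring, in that causal order. The
default parameter set (`default_paper_params()`) targets the printed facts of
the published 734-patient cohort:

* covariate marginals match the printed table: age normal 63.1/10.7 truncated
  to 20-92 years, baseline lymphocyte count truncated normal 1.6/0.6 above
  0.3 (10^3 cells/uL), planning target volume log-normal moment-matched to
  mean 612.3 / SD 279.3 cm^3 (the printed minimum of 92.8 implies right skew;
  a truncated normal would distort the upper tail), and printed level
  frequencies for the categorical fields;
* the exposure-model intercept is back-solved so 36.1% of patients receive
  protons; slopes encode the printed imbalances (older patients, smaller
  target volumes and more chemotherapy cycles tilt toward protons);
* the mediator model's intercept and exposure coefficient are back-solved
  jointly so marginal G4RIL prevalence is 45.2% under photons and 22.6% under
  protons; covariate slopes take the printed multivariable odds ratios where
  available;
* the outcome model fixes the direct-effect hazard ratio at 0.79 and the
  mediator hazard ratio at 1.49 (no exposure-mediator interaction), covariate
  slopes follow the printed multivariable hazard ratios, and the intercept is
  back-solved so the photon-arm latent median survival is 40.9 months.

These coefficients are calibration targets, not ground truth recovered from
the real data. One consequence: the generator's *implied* indirect-effect
hazard ratio, from the prevalence pair and the 1.49 mediator effect, is about
0.92 — the published joint fit reported 0.95 — so simulated proportions
mediated land near 0.25-0.30 rather than the published ~14.5%. Censoring is
administrative, Uniform(12, 168) months, independent of everything: the
source never describes its follow-up mechanism, accrual spanned 2004-2017
with analysis a few years later, and independence is the weakest assumption
under which the Kaplan-Meier and regression machinery stays valid. What the
generator does **not** emulate: weekly lymphocyte trajectories (the mediator
is reduced to its grade-4 indicator), dosimetric features, dependent
censoring, non-exponential baseline hazards, and calendar-time effects.
Passing tests on this generator therefore demonstrate correctness of the
estimators under the assumed model, not robustness to the ways real cohorts
violate it.

Reproducibility: one integer master seed; every stochastic stage
(covariates, exposure, mediator, outcome, censoring, bootstrap) consumes a
named substream derived from it (`substream_seed()`), so the draws a stage
sees do not change if stages are added or reordered.

## Numerical choices and degenerate inputs

* Logistic fits run IRLS to relative tolerance $10^{-12}$; separation
  (a fitted probability numerically 0/1 or a coefficient beyond 15 on the
  log-odds scale) and rank deficiency are hard errors naming the columns —
  odds-ratio tables must not be built on divergent fits. The exponential AFT
  fit is accepted only if its analytic score vanishes at the optimum; Cox
  models use Efron ties (Breslow available) with tolerance $10^{-10}$.
* `log(1+e^x)` is computed overflow-safely, so extreme linear predictors in
  the closed-form effects stay finite.
* Kaplan-Meier confidence bands use Greenwood variance on the log-log scale,
  which makes the median interval Brookmeyer-Crowley; the published analysis
  does not state its method, so this is a documented choice, not a replica.
* Cohort summaries use Welch's t by default (the source says only "t tests";
  unequal variances is the safer default and the pooled test is a switch) and
  Pearson chi-squared with continuity correction on 2x2 tables only, matching
  the convention of the original analysis environment (both configurable).
* Strata with no events are skipped with a warning in subgroup analyses;
  strata with fewer events than a configurable floor are flagged
  underpowered rather than suppressed.
* The exposure-mediator interaction $\theta_3$ is off by default — the source
  model statement has no interaction term — but it is a one-line switch and
  both settings are tested; conditioning values `c_cond` default to the
  sample means of the adjustment covariates (in the pipeline: the mean
  propensity score in the matched cohort).

## Problem sizes used by the checks

The test suite and acceptance script exercise: closed-form-vs-oracle
agreement on 100 random parameter draws (two-point summation to $10^{-10}$;
Monte-Carlo with $10^6$ draws within 3 MC standard errors); interval coverage
for the log NIE over 500 replicates of n = 2000 single-covariate cohorts;
parameter recovery at n = 5000 (and n = 50 000 for the generator's own
recovery property); matching optimality against exhaustive enumeration on
8x8 instances and against greedy on instances of about one hundred patients
per arm; and the full pipeline
at n = 400-5000. These sizes were chosen to make sampling error small
relative to the assertions' tolerances while keeping a default test run
comfortably interactive.

## Known limitations

* Mediation is exponential-AFT only; no Cox-based (rare-outcome) mediation,
  multiple mediators, time-varying covariates, competing risks, or
  sensitivity analysis for unmeasured mediator-outcome confounding
  (E-values). A free-shape Weibull outcome is exposed for sensitivity use
  (`fit_exp_aft(..., free_shape = TRUE)`, `to_hazard_scale(shape = )`) but is
  not wired into `mediate()`.
* The matching solver is exact for scalar (one-dimensional) distances, which
  covers propensity scores; it is not a general multivariate assignment
  solver.
* 1:1 matching without replacement only; no weighting (IPW) estimators.
* The generator's fidelity claims extend only to the printed marginals and
  effect targets listed above.
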