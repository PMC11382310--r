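# rilmed

Causal mediation analysis of censored survival outcomes, built around one
clinical question: when patients with esophageal cancer receive proton beam
therapy (PBT) instead of photon (IMRT) chemoradiation, how much of the
observed overall-survival benefit flows *through* the reduced incidence of
grade 4 radiation-induced lymphopenia (G4RIL), and how much is a direct
effect of the modality? The package is aimed at biostatisticians and
radiation-oncology researchers who want the full analysis chain — cohort
validation, confounder screening, propensity-score optimal matching,
censored-data regression, and the natural-effect decomposition — as small,
composable, pipe-friendly functions, plus a synthetic cohort generator so
every stage can be exercised and calibrated without access to protected
patient data.

## The model

For exposure $A$ (1 = PBT, 0 = IMRT), binary mediator $M$ (G4RIL), censored
survival time $T$, and adjustment covariate(s) $C$ (here: the propensity
score), two regressions are fit on the matched cohort:

- mediator: $\text{logit}\,P(M=1 \mid A, C) = \beta_0 + \beta_1 A + \beta_2' C$
- outcome (exponential AFT, Weibull shape fixed at 1):
  $\log T = \theta_0 + \theta_1 A + \theta_2 M + \theta_3 AM + \theta_4' C + \varepsilon$

Writing $L_x = \beta_0 + \beta_1 x + \beta_2'c$ and $k_x = \theta_2 + \theta_3 x$,
the natural direct and indirect effects on the time-ratio scale have closed
forms obtained by summing the counterfactual expectation over the Bernoulli
mediator:

$$\text{TR}_{NIE} = \frac{(1+e^{L_a+k_a})(1+e^{L_{a^*}})}{(1+e^{L_{a^*}+k_a})(1+e^{L_a})},
\qquad
\text{TR}_{NDE} = e^{\theta_1(a-a^*)}\,\frac{1+e^{L_{a^*}+k_a}}{1+e^{L_{a^*}+k_{a^*}}}.$$

With shape 1, $\log \text{HR} = -\log \text{TR}$, and the decomposition
$\text{HR}_{TE} = \text{HR}_{NDE} \cdot \text{HR}_{NIE}$ holds exactly.
Confidence intervals come from the delta method over the stacked
$(\beta, \theta)$ (or a pair-resampling bootstrap). Two derived summaries are
reported: the proportion mediated on the excess-relative-hazard scale,
$\text{PM} = e^{NDE}(e^{NIE}-1) / (e^{NDE+NIE}-1)$ (log-HR arguments), and
the indirect effect converted to months of median survival by scaling the
reference-arm exponential hazard:
$\Delta = (\ln 2/\lambda)(1/\text{HR}_{NIE} - 1)$.

Matching is exact optimal 1:1: the pairing of treated to distinct controls
minimizing the total absolute propensity-score distance (logit scale by
default), solved by a dynamic program over the score-sorted arms and verified
against exhaustive enumeration in the tests.

## Worked example

```r
library(rilmed)

cohort <- simulate_cohort(default_paper_params(n = 734), seed = 2024)
ps     <- fit_ps_model(cohort)                  # backward Wald elimination
pairs  <- optimal_match(ps, cohort)             # exact optimal 1:1
matched <- matched_cohort(cohort, pairs)

fit_table(fit_logistic(matched, g4ril ~ modality))
med <- mediate(matched, ps = ps$scores[match(matched$id, cohort$id)])
med
```

```
<ps_model> modality ~ age + ptv + barretts + surgery  (forced: age, surgery; wald criterion)
261 matched pairs, total logit distance 11.699

  term        ratio conf.low conf.high  p.value label
1 (Intercept) 0.992    0.779     1.26  9.51e- 1 0.99 (0.78-1.26; P = 0.951)
2 modality    0.294    0.202     0.430 2.31e-10 0.29 (0.20-0.43; P = 0.000)

<mediation_result> n = 522, events = 338 (delta CIs)
  NDE HR 0.764 (95% CI 0.612-0.955; P = 0.0182)
  NIE HR 0.870 (95% CI 0.816-0.928; P = 0.0000)
  TE  HR 0.665 (95% CI 0.535-0.828; P = 0.0003)
  proportion mediated 0.296
  mediated median-survival gain 5.80 months (95% CI 3.00-8.77)
```

Reading this: protons cut the odds of G4RIL by ~70% in the matched synthetic
cohort (OR 0.29). The survival benefit decomposes into a direct hazard ratio
of 0.76 and an indirect, G4RIL-mediated hazard ratio of 0.87; about 30% of
the total effect travels through the mediator, worth ~5.8 months of median
survival in this simulated cohort. `tidy(med)`, `glance(med)` and
`autoplot(med)` give the tabular and graphical views;
`subgroup_mediation(matched, "surgery", ...)` repeats the analysis within
surgical strata.

The same chain runs end to end from one config:

```r
run_pipeline(default_config(n = 734, seed = 1, output_dir = "out"))
```

writes the cohort summary, screening report, matched pairs, balance table,
odds-ratio/hazard-ratio tables, Kaplan-Meier step functions, mediation and
subgroup JSON, and a checksum manifest. A shell wrapper with `simulate`,
`match`, `mediate`, `run`, and `report` subcommands lives at
`system.file("cli", "rilmed.R", package = "rilmed")`.

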