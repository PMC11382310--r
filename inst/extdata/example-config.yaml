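# Example pipeline configuration: simulate a small cohort at the calibrated
# defaults, match, and mediate. Override the destination with `--out`.
input:
  simulate:
    n: 300
screening:
  candidates: [age, sex, baseline_alc, ptv, ecog, location, stage,
               chemo_cycles, barretts, histology, surgery]
  alpha: 0.05
propensity:
  forced: [age, surgery]
  criterion: wald
  distance_scale: logit
mediation:
  interaction: false
  ci_method: delta
subgroup:
  strata: surgery
  min_events: 5
output_dir: rilmed-out
seed: 3
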