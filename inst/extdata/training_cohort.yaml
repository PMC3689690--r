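# Default cohort configuration: training-column summary statistics of the
# VA eye-clinic chart-review cohort (n = 351). Continuous predictors are
# truncated normals parameterized by the published mean/SD; flags are
# Bernoulli prevalences. Transition rates: 7.7%/yr retinopathy onset,
# 0.7%/yr PDR -> vision loss, entrants without retinopathy with p = 0.715,
# no routine pan-retinal photocoagulation. The logistic hazard carries the
# three significant odds ratios; its intercept is calibrated at run time to
# a 26.5% PDR prevalence.
"n": 501   # quoted: a bare n is YAML-1.1 boolean "no"
specs:
  age: {family: normal, mean: 67.5, sd: 9.4, lower: 21, upper: 100}
  male: {family: bernoulli, p: 0.983}
  dm_duration: {family: normal, mean: 21.5, sd: 9.0, lower: 0, upper: 80}
  bmi: {family: normal, mean: 32.2, sd: 6.3, lower: 12, upper: 70}
  hba1c: {family: normal, mean: 8.2, sd: 1.8, lower: 4, upper: 18}
  hypertension: {family: bernoulli, p: 0.980}
  dyslipidemia: {family: bernoulli, p: 0.843}
  nephropathy: {family: bernoulli, p: 0.353}
  tobacco: {family: bernoulli, p: 0.251}
rates:
  onset_annual: 0.077
  vl_annual: 0.007
  entrant_no_dr: 0.715
  prp_annual: 0.0
hazard:
  odds_ratios: {dm_duration: 1.059, nephropathy: 2.163, bmi: 0.961}
  intercept: calibrate
target_pdr_prevalence: 0.265
hazard_scale: 1.0
record_history: false
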