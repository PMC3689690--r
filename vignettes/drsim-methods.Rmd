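---
title: "drsim: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{drsim: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drsim)
```

## The model

`drsim` simulates a cohort of diabetic patients attending an eye clinic,
each as an autonomous agent on a five-state statechart: (1) no retinopathy,
(2) non-proliferative diabetic retinopathy (NPDR), (3) proliferative
diabetic retinopathy (PDR), (4) legal vision loss (VL), (5) death. Death is
absorbing and reachable from every living state; VL can only progress to
death; the single backward edge among living states is PDR → NPDR,
representing pan-retinal photocoagulation (PRP). Time advances in annual
steps. Each year a living agent:

1. ages one year and accrues one year of diabetes duration;
2. draws against the life-table death probability `qx` at its *new* age;
3. if alive, draws one uniform `u` and advances iff `u < p` for its
   state-specific annual probability: the constant onset rate from state 1,
   the agent's logistic probability from state 2, the constant vision-loss
   rate from state 3;
4. if it *began the year* in PDR and is still there, draws against the
   annual PRP probability and reverts to NPDR on success.

Only age and duration evolve; BMI, HbA1c and the comorbidity flags are
frozen at generation. This mirrors the annual-update event of the original
clinical model, which updates exactly those two fields.

The NPDR → PDR probability is logistic,
\[
p(x) = \frac{1}{1 + e^{-(\beta^\top x + m)}},
\]
with β restricted to the three predictors found significant in the source
cohort (per-year diabetes-duration OR 1.059, nephropathy OR 2.163, per-unit
BMI OR 0.961 — the counterintuitive protective BMI effect is a truncation
artifact of the underlying clinic data and is reproduced as-is, not
corrected). The remaining predictors are carried as demography. A config
option accepts any coefficient map over the nine profile fields.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `onset_annual` | 0.077 | 1/yr | administrative-data incidence of retinopathy onset among diabetics |
| `vl_annual` | 0.007 | 1/yr | annualized published incidence of vision loss from PDR |
| `entrant_no_dr` | 0.715 | prob. | population share of diabetic adults without retinopathy (1 − 0.285) |
| `prp_annual` | 0 | 1/yr | the reported 10-year run shows PDR accumulating, implying PRP was not routinely applied; off by default |
| `target_pdr_prevalence` | 0.265 | prob. | PDR share of the training cohort (93/351); calibration target for the intercept |
| `hazard_scale` | 1 | — | see "prevalence as hazard" below |
| life table | Gompertz, b = 0.09/yr | — | male baseline set in closed form so 10-year survival from age 67 is 0.65 |

## The unpublished intercept

The source model's odds ratios are published but its intercept `m` is not.
`calibrate_intercept()` closes the gap: the mean of `plogis(m + βᵀxᵢ)` over
any fixed profile set is continuous and strictly increasing in `m`, so the
intercept reproducing a target prevalence exists and is unique; we find it
by bracketed root-finding (`uniroot`, bracket `±40` beyond the range of the
linear predictor, tolerance `1e-12` on `m`, verified to `1e-8` on the
achieved mean). `generate_cohort()` calibrates on the very profiles being
assigned, so the cohort-mean predicted probability equals the target
exactly and the realized PDR count is Binomial(n, 0.265).

**Prevalence as hazard.** The upstream design reuses the cross-sectional
predicted probability (a prevalence model) as the *annual* NPDR → PDR
transition probability. These are different quantities; with a mean annual
probability of 0.265, surviving agents pile up in PDR within a decade. We
replicate the reuse faithfully rather than silently correcting it, and
expose `hazard_scale` (multiplying the annual probability) for users who
want to decouple the two. This is why only the *direction* of the 10-year
outcomes (more PDR among survivors; deceased older but with shorter
diabetes duration) is asserted, not the published counts.

## The synthetic cohort generator

The real cohort survives only as a summary table, so the generator samples
each predictor independently from a moment-parameterized family — truncated
normal by default (bounds: age [21, 100], duration [0, 80], BMI [12, 70],
HbA1c [4, 18], making the acknowledged low-end truncation of the BMI data
explicit), lognormal and gamma moment-matched alternatives, Bernoulli
flags — with rejection sampling against the bounds and against the joint
constraint `dm_duration ≤ age − 18` (diabetes onset no earlier than
adulthood; duration is resampled for offending rows, and 1000 fruitless
rounds raise a configuration error). The generator emulates:

* the published marginal moments and prevalences (training column);
* the stage mix, via calibrated logistic assignment (validation mode keeps
  the no-retinopathy state empty, matching a cohort of diagnosed patients;
  steady-state mode fills it with probability 0.715);
* the chart-abstraction pipeline (`generate_abstraction_fixture()`: 535
  records, 34 excluded for missing duration, 70/30 split → 501 → 351/150).

It does **not** emulate predictor correlations (none are published beyond
what the age–duration constraint induces), within-patient trajectories of
BMI/HbA1c, eye-level disease, or NPDR substaging. A green validation test
therefore establishes marginal fidelity, not joint fidelity.

## Validation battery and its calibration

`validate_cohort()` replicates the ten-variable comparison: Student's
pooled-variance *t* from summary statistics for the four continuous
predictors (Welch by flag), Pearson χ² without continuity correction for
the five flags and the NPDR/PDR split (Yates by flag); pass means
p > 0.05. Printed reference p-values are consistent with either t/χ²
variant at their reported precision, so the defaults follow the named
tests. No multiple-testing adjustment is applied, matching the original
per-variable criterion; with ten tests the family-wise false-alarm rate
under the null is correspondingly higher.

Two edge conventions: zero variance in both groups gives t = 0, p = 1 when
means agree (infinite t, p = 0 otherwise); a 2×2 with a zero column
marginal — both cohorts unanimous on a near-100% trait such as
hypertension — is recorded as χ² = 0, p = 1, since observed equals expected
exactly. `chi_square_test()` itself refuses zero-marginal tables and
suggests an exact test.

Type-I calibration is asserted under a *resampled-reference* null: each
replicate draws both the 501-agent cohort and a fresh 150-record reference
from the same configured world. Against a fixed reference summary the
rejection rate is far below α by construction (the two-sample denominator
overstates the sampling variance of the comparison), so the resampled
design is the one under which a 5% rate is meaningful. The χ² rate is
asserted only for variables meeting the standard expected-cell-count ≥ 5
rule at n = 150; the male (98.7%) and hypertension (99.3%) tables have
expected minority cells of 2–3, where the Pearson approximation is known to
be invalid — a property of the test, not of the implementation.

## Mortality

`load_life_table()` reads `age,qx_male,qx_female` CSVs (ages contiguous
from 0; the terminal row is forced to `qx = 1` with a warning; lookups use
`floor(age)` — no interpolation rule is published — and return 1 beyond the
table). Because the source table's year and vintage are unstated, the
packaged default is a synthetic Gompertz surrogate,
`qx(a) = 1 − exp(−a·e^{b·age})` with b = 0.09/yr and the male baseline
solved in closed form so that 10-year survival from age 67 is 0.65 — the
realized survival of the reference cohort (327/501) — with the female
baseline 0.8× the male. It is a calibration surrogate, not actuarial data;
any period table in the CSV layout can be substituted.

## Numerical and design choices

* **Event order** (increment → death → progression → PRP) is unstated
  upstream; chosen so mortality uses the updated age and at most one state
  transition occurs per agent-year, and unit-tested. PRP applies only to
  agents that began the year in PDR, so a same-year NPDR → PDR → NPDR
  bounce (invisible in yearly tallies) cannot occur.
* **Advancement test** is strict: advance iff `u < p`.
* **RNG**: one global seeded stream; draws are consumed in a documented
  order (per year: one mortality uniform per living agent in row order,
  one advancement uniform per survivor, one PRP uniform per continuing PDR
  agent), so a config plus seed reproduces every output byte-identically.
* **Logistic fitting** is iteratively reweighted least squares with
  relative log-likelihood tolerance `1e-10` and a 100-iteration cap; Wald
  95% CIs on the OR scale (`exp(β̂ ± 1.96·SE)`), matching conventional SAS
  logistic output. Singular designs error; fits whose fitted probabilities
  saturate numerically at 0/1 (separation) are returned with
  `converged = FALSE` and a warning.
* **History** records entry and state changes only — sufficient for
  first-passage and "ever reached VL" queries while keeping large runs
  lean — and is off by default.
* **Entrants** default to 0 per year, so a 10-year run follows the closed
  cohort of 501 initial agents.

## Known limitations

Independent predictors (no published correlation structure); prevalence
reused as annual hazard (above); a surrogate life table rather than the
original actuarial one; NPDR treated as a single stage (mild/moderate/
severe substaging lacked significance in the source data); no clinic
capacity, screening-interval or cost modelling. The non-significance
validation criterion itself cannot demonstrate equivalence — absence of
evidence of a difference at n = 150 is weaker than a TOST-style equivalence
bound — and is replicated verbatim, limitations included.
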