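---
title: "Modelling national CKD burden with patient-level microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling national CKD burden with patient-level microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdsim)
```

## The model

`ckdsim` projects the clinical burden of chronic kidney disease (CKD) for a
country over the 2022–2027 horizon with a discrete-time, individual-level
Monte Carlo simulation. A closed cohort of virtual individuals is drawn so
that its marginals match a *country input bundle* — national population,
sex × age-band pyramid, the joint KDIGO (G × A) stage distribution
conditional on age band and sex, stage-specific diagnosed fractions, and
comorbidity prevalence conditional on CKD status. Each calendar year every
living individual is updated in a fixed sub-step order:

1. ageing (+1 year);
2. eGFR decline by a subtype-specific annual slope, with restaging against
   the KDIGO cut-points, and an annual albuminuria (A-stage) transition;
3. incident CKD onset among CKD-free adults;
4. comorbidity (type 2 diabetes / hypertension) onset, if enabled;
5. diagnosis of prevalent undiagnosed cases (absorbing);
6. cardiovascular events — heart failure, myocardial infarction, stroke —
   drawn as independent Bernoulli events with probability
   `min(1, base_rate(age band, sex) × rr(KDIGO category))`;
7. kidney replacement therapy (KRT): initiation below an eGFR threshold
   subject to an access probability, a modality draw
   (haemodialysis / peritoneal dialysis / transplant) and annual
   inter-modality transitions;
8. all-cause mortality, with the same KDIGO-category relative-risk
   structure and an optional transplant-specific multiplier.

Death and diagnosis are absorbing; dead individuals are never updated
again. Because the cohort is closed (no births, migration or annual entry
of 18-year-olds), counts are rescaled post hoc to the national population:
`count × national_pop / virtual_size`. The per-100,000 prevalences this
yields are algebraically identical to computing rates on the virtual cohort
directly, which is how the package reports them.

### Kidney arithmetic

eGFR is computed with the CKD-EPI creatinine equation; both the 2009 and
the race-free 2021 coefficient sets are supported and selected per bundle
(default 2021), since source data vintage differs between countries. G
intervals are closed at the lower bound (eGFR 60 → G2, 45 → G3a); A2 is the
closed interval [30, 300] mg/g and A3 is (300, ∞), so albuminuria above
30 mg/g marks disease onset. These boundary conventions are fixed here
because staging sources typically leave them implicit. eGFR is floored at
zero, and individuals below the G5 threshold remain G5 until KRT or death.

The KDIGO risk grid ships with the published 2012 heat-map categorisation
of all 18 (G, A) cells. The per-category relative risks for events and
death are bundle inputs; the packaged defaults (1 / ~1.4–1.5 / ~2 / ~3–4.5
from low to very high) express the usual steep KDIGO gradient and are meant
to be replaced by country-specific estimates.

## Randomness, determinism and common random numbers

Each projection uses one master seed. The baseline cohort is drawn from it,
and each simulated year derives its own stream seed. Within a year the
engine draws one fixed-length uniform vector per sub-step — one draw per
individual, in id order, whether or not the individual is eligible for the
transition. This has three consequences:

* results are bit-reproducible given (bundle, n, seed);
* they do not depend on row order or on how many individuals happen to be
  eligible for earlier sub-steps;
* two scenario runs with the same seed consume identical uniforms at every
  (individual, year, sub-step), so scenario contrasts are exact
  common-random-numbers comparisons. This is what makes diagnosed
  prevalence provably non-decreasing in the diagnosis-rate multiplier at
  every year of the ±10% sensitivity analysis, per individual path.

Diagnosis status is a label with no feedback on progression, events or
mortality in this implementation, so sensitivity scenarios differ only in
the diagnosed/undiagnosed split; this mirrors an assumption that detection
alone (without modelled treatment) does not alter the disease course, and
it is the conservative reading of an unspecified mechanism.

## Parameters that matter

| Parameter | Units / default | Notes |
|---|---|---|
| `slopes` | mL/min/1.73 m²/yr; −1.0 to −4.0 | keyed by (T2D, HTN, prior CV event); identical across countries in a multi-country run |
| `diagnosis_rate_by_stage` | annual probability per G stage | doubles as the baseline diagnosed fraction; rises steeply with stage |
| `kdigo_grid$rr` | multiplier ≥ 0 per (category, outcome) | `rr(low, ·) = 1` by convention |
| `krt$egfr_initiation_threshold` | mL/min/1.73 m²; 10 | initiation eligibility |
| `krt$access_probability` | fraction; 1 | the main calibration knob |
| `a_transition` | 3×3 row-stochastic; identity | annual A-stage transition; identity means albuminuria stage is retained, since no ACR slope is modelled |
| `onset_stage_distribution` | 50/50 (G2, A2)/(G3a, A1) | entry stage of incident cases |
| `comorbidity_incidence` | annual probability; 0 | comorbidities fixed at baseline unless enabled |

Within a stage cell, concrete eGFR and ACR are drawn uniformly (G5 bounded
at [1, 15), A3 at (300, 3000]); only stage-level distributions are
typically published, so the uniform is the least-informative choice that
keeps staging and measures mutually consistent. When an A-stage transition
occurs, the concrete ACR is re-anchored at the new cell midpoint — ACR
enters the model only through its stage.

Diagnosis rates are specified per G stage only; published diagnosis-rate
sources are G-stage-resolved, and nothing in the engine requires A-stage
resolution.

## Calibration

KRT prevalence targets are obtained by ordinary least squares through
historical (year, count) datapoints, evaluated at the target year (a
log-linear option exists for settings with exponential growth; the
regression family is a config flag because sources rarely state it, and
calibration targets counts by default). Scaling knobs (`krt_access`,
`ckd_incidence`, `diagnosis`) are then tuned by bisection against the
target, with the simulator held at a fixed seed so the search sees a
deterministic monotone function. Calibration runs are intended at reduced
cohort size (~1e5) with the final projection at full size.

## The synthetic-data generator

No real country inputs ship with the package, so `generate_bundle()`
produces bundles whose statistical structure mirrors the observed
cross-country baseline tables: an even sex split, four reporting age bands
(0–17, 18–34, 35–64, 65+), all-stage CKD prevalence rising with age into
the observed 5.5–18.8% national range, roughly a fifth of prevalent cases
diagnosed with a steep stage gradient, and CKD-conditional comorbidity
prevalence near the observed weighted means (T2D ≈ 26%, hypertension
≈ 60%). The `small_aged` and `large_young` profiles pin the 65+ population
share at the two observed national extremes (28.9% and 3.6%); `degenerate`
is a point-mass, zero-rate bundle whose projections are exactly static —
the engine's null test. `generate_ground_truth_scenario()` packages
closed-form expectations alongside a bundle: survival 0.9⁵ = 0.59049 after
five years of constant hazard 0.1, a death-rate ratio of 2 between
very-high and low KDIGO categories, mean eGFR 75 − 3k after k years of
slope −3, and a KRT access multiplier of 0.6 recoverable by bisection.

What the generator does *not* emulate: real joint dependence between
comorbidities and stage (comorbidities are drawn independently of stage
given CKD status, as only CKD-conditional prevalences are published),
secular trends in incidence, within-country heterogeneity beyond age band
and sex, and migration or fertility. Passing tests on synthetic bundles
therefore validate the *mechanics* of the engine and the estimators — not
the realism of any particular country's inputs.

## Numerical and design choices

* Under-18s are synthesized without CKD state (the eGFR equation is
  adult-only) and age into eligibility; they are included in the cohort so
  national per-100k denominators are total-population denominators.
* CKD is treated as absorbing at the person level: a prevalent case never
  reverts to "no CKD" even if its albuminuria stage regresses.
* Events within a year are drawn independently given the start-of-year
  state; a cardiovascular event changes the progression subtype from the
  *next* year (the slope sub-step precedes the event sub-step).
* Multiplied probabilities are capped at 1; caps on diagnosis rates are
  recorded and reported by the sensitivity driver.
* Bisection brackets must straddle the target, and exhausting `max_iter`
  is an error that reports the best iterate, so silent non-convergence is
  impossible.
* Cross-country weighted means use the national CKD population (diagnosed
  + undiagnosed) of the target year as weights; with the shipped reference
  tables this reproduces the published cardiovascular weighted means to
  within 0.1%.
* The UAE enters the 31-country rollup through its Emirati population
  only, matching the reference tables' reporting convention.

## Problem sizes used in the tests

Marginal-recovery and ground-truth tests run at n = 1e4–1e5, where three
binomial standard errors give sub-percentage-point resolution; the
scale-stability check compares per-100k outputs between n = 1e5 and
n = 1e6. These sizes give tight Monte Carlo error while keeping the suite
quick on a laptop; the engine is vectorised, so full 2×10⁷-person national
cohorts differ only in wall time and memory, not in code path.

## Known limitations

* All-cause mortality only; no cause-specific decomposition or competing
  risks.
* Annual cycles; within-year event ordering is a modelling convention, not
  data.
* No health-economics (cost) outputs.
* The diagnosed/undiagnosed split carries no treatment effect, so the
  model cannot by itself quantify the benefit of earlier diagnosis — only
  the size of the undetected population.

## A worked example

```{r example, eval = FALSE}
bundle <- generate_bundle("small_aged", seed = 1)
proj <- run_projection(bundle, n = 2e4, seed = 42)
proj
projection_prevalence_per_100k(proj)

tabs <- load_reference_tables()
rollup_total_cases(tabs, 2027) / 1e6     # total national cases, millions
undiagnosed_share(tabs, 2027)$weighted_share
cv_weighted_means(tabs)
```
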