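---
title: "Auditing DOAC dose guideline concordance: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing DOAC dose guideline concordance: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doacaudit)
library(dplyr)
```

## The problem

Direct-acting oral anticoagulants (DOACs) — dabigatran, rivaroxaban, and
apixaban — carry label-based dose-reduction rules for non-valvular atrial
fibrillation (NVAF). Each drug has exactly one full and one low regimen,
and the label says who should get which:

* **dabigatran** 150 mg BID (full) vs 75 mg BID (low): low dose if
  eGFR < 30 mL/min/1.73 m²;
* **rivaroxaban** 20 mg QD (full) vs 15 mg QD (low): low dose if
  eGFR < 50;
* **apixaban** 5 mg BID (full) vs 2.5 mg BID (low): low dose if at least
  two of \{age ≥ 80 years, weight ≤ 60 kg, serum creatinine ≥ 1.5 mg/dL\}.

A dose audit asks, for every treated patient, whether the dispensed
regimen matches the rule-recommended one, and then profiles discordance by
drug, site of care, calendar year, and patient-level predictors.
`doacaudit` implements that audit as a tested pipeline over five
EHR-shaped tables (patients, diagnoses, labs, vitals, dispensings), plus a
seeded synthetic-EHR generator so every stage can be exercised without
access to protected health data.

## Cohort construction

Patients qualify with at least one atrial-fibrillation code and no
valvular-disease code (the code map is pluggable; a synthetic default
ships with the package). Exclusions are applied in a fixed order, each
patient attributed to the first step it fails: under 30 days of total DOAC
supply; any venous-thromboembolism code; more than one DOAC, more than one
dose category, or more than one dispensing site; only unclassifiable
regimens (e.g. rivaroxaban 10 mg); missing demographics; missing index
creatinine (plus, for apixaban, missing index weight). The waterfall log
satisfies a conservation identity (initial N = final cohort + per-step
exclusions) and the final membership is invariant to the step order even
though per-step counts are not. Patients excluded for multiple
drugs/doses are retained in a side table because they feed the dose-switch
analysis.

All derived variables are anchored at the **index date**, the first
qualifying fill. The index creatinine is the most recent value dated on or
before the index — same-day values count, because the prescriber sees
them. A tie on the most-recent date is broken by the larger creatinine,
which is conservative in the sense of leaning toward a low-dose
recommendation; the alternative (smaller value) changes no bundled result
but the choice is centralised in `select_index_lab()`.

## Clinical scores

eGFR uses the 4-variable MDRD study equation with the IDMS-traceable
coefficient,

$$\mathrm{eGFR} = 175 \cdot \mathrm{Scr}^{-1.154} \cdot
\mathrm{age}^{-0.203} \cdot 0.742^{[\mathrm{female}]} \cdot
1.212^{[\mathrm{Black}]},$$

because that is the form behind the automatic eGFR most US laboratories
(including the VA's) reported in the DOAC era; the original 186
coefficient is available via `mdrd_coefficient = 186` for sensitivity
analyses, and no CKD-EPI or Cockcroft–Gault variants are offered. The
implementation is checked against a 100-point grid evaluated with 50-digit
arithmetic to a relative error below 1e-10.

CHA₂DS₂-VASc uses the published points (CHF 1, hypertension 1, age ≥ 75 2,
diabetes 1, stroke/TIA 2, vascular disease 1, age 65–74 1, female 1). The
Elixhauser burden is a count of distinct conditions from the code map's
Elixhauser class. All category bins (age, BMI, eGFR, Elixhauser,
regression covariates) are left-closed and right-open except the top bin,
so printed labels such as "75–84 / ≥ 85" are read as [75, 85) and
[85, ∞); every raw value maps to exactly one bin and out-of-range values
are errors, never silent `NA`s.

## Dose rules and the apixaban lattice

`classify_dispense()` is exhaustive over (drug, dose, frequency):
anything outside the six defined regimens is `OTHER` (dabigatran 110 mg
deliberately so — it was not used for NVAF in the source system).
`recommend_dose()` applies the thresholds exactly as printed: strict
inequalities for the renal cutoffs (eGFR 30.0 on dabigatran is FULL) and
inclusive boundaries for all three apixaban criteria (age 80, weight 60 kg
and creatinine 1.5 mg/dL all count). The three apixaban flags define a
lattice of eight mutually exclusive groups (none; three singles; three
pairs; all three) used to stratify the predictor models, since the
criteria deterministically set the recommendation and cannot be entered as
covariates.

## Aggregation conventions

Percents in all published-style tables are integers rounded **half away
from zero** (`round_half_up()`): the convention was verified against every
printed count/percent pair in the source tables (22.80→23, 6.52→7,
6.29→6), and base R's banker's rounding would get several cells wrong. A
zero denominator yields an `NA` percent, never 0. Site profiles include
only sites meeting a minimum denominator — defaults 100 patients for the
full-dose-recommended direction and 20 for the low-dose-recommended
direction — and the reported range is over included sites only. Trend
tables attribute each patient to the calendar year of the first fill, so
each patient appears in exactly one year; whether the source audit counted
by first-fill year or fills-in-year is not stated, and first-fill
attribution was chosen because it keeps the per-year denominators a
partition of the cohort.

## Predictor models

Within each recommended-dose stratum (per drug, and per apixaban group),
discordant dosing is modelled by maximum-likelihood logistic regression
with all covariates entered simultaneously: age bins, sex, race, region,
body-size bins, six comorbidity flags, renal or criterion-specific bins,
and Elixhauser bins. Effects are reported as adjusted odds ratios with
Wald 95% intervals (normal approximation on the log-odds scale,
exponentiated) — the source tables do not state their CI method, and Wald
is the standard default matching the table format. No multiple-testing
adjustment is applied, matching the source analysis. Age 80 goes in the
top age bin (the printed bins "75–79 / > 80" leave it unassigned;
the accompanying text says "age 80+"). Model discrimination is the
c-statistic, computed by ranks and therefore invariant to monotone
transformations of the fitted probabilities.

Degenerate inputs fail loudly: empty declared covariate levels,
single-class outcomes, aliased coefficients, apparent complete separation
(|log-odds| > 15), and IRLS non-convergence are all errors naming the
culprit — no continuity corrections are applied. The orchestrator
`run_all_models()` drops covariates that are constant within a stratum
(their AOR is inestimable there), collapses declared-but-unobserved
levels, and reports inestimable strata with an explicit skip reason
rather than omitting them.

## The synthetic-EHR generator

`generate_cohort()` draws a DOAC-treated NVAF cohort whose marginals
follow the published cohort's characteristics table: 2% female, 86/8/6%
White/Black/Other, the four-region split, the published age, BMI, eGFR
and Elixhauser category frequencies, and six comorbidity prevalences.
Fill-year weights follow the published uptake curve (92 patients in 2010
growing to about 31,000 in 2016), with each drug only available from its
market-entry year. Covariates are drawn independently except two coupled
blocks: (height, BMI, weight), and (age, sex, race, eGFR, creatinine) —
creatinine is obtained by inverting the MDRD equation at the sampled eGFR,
so the emitted labs, the derived renal categories, and the dose rules are
internally consistent by construction, and the audit reproduces the
generator's truth labels exactly.

Received doses are recommended doses flipped with probability
`plogis(intercept + bin offsets + site offset)`. The default model was
calibrated once so the generated cohort lands at the published marginal
rates — about 6% low-dose among full-dose-recommended patients and about
23% full-dose among low-dose-recommended patients — with discordance
concentrated in old age and near-cutoff renal function, as observed. Site
offsets default to zero; site variation is opt-in (`site_effects`), so
parameter-recovery tests are not attenuated by unmodelled site
heterogeneity.

What the generator does **not** emulate: real coding practice (the
bundled code map is synthetic), visit-level longitudinal structure beyond
a handful of dated records per patient, correlations among comorbidities,
within-patient creatinine trajectories, or any joint covariate structure
beyond the two coupled blocks (the source reports marginals only). Tests
passing on synthetic data therefore certify the audit's arithmetic,
rules, and statistical machinery — not robustness to real-world coding
noise.

Deterministic complements: `make_fixture()` re-expands a table of
(year, drug, site, counts) into patient-level archetypes whose covariates
force the required recommendation, so published count tables can be
pushed through the complete pipeline and reproduced exactly;
`make_switch_fixture()` does the same for the excluded-rivaroxaban switch
analysis. Same-day fills of both rivaroxaban strengths are resolved by
deeming the higher strength first (and flagging the tie); the source does
not address ties.

## Problem sizes and numerical choices

The bundled checks use the published tables at full size (fixtures of
roughly 68,000–74,000 synthetic patients run through the audit in
seconds) and parameter recovery at n = 25,000 patients × 20 seeded
replicates, at which size the Wald intervals cover the injected
coefficients at their nominal rate (measured 95–100% per coefficient).
Marginal-fidelity checks run at n = 10,000 against a three-standard-error
band. Sampled continuous values keep a small margin (0.05–0.25 units)
away from category boundaries so that floating-point round trips through
CSV can never flip a category. Seeding uses a single integer; identical
(config, seed) gives byte-identical tables.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_patients = 20000, n_sites = 12,
  site_effects = 0.4, seed = 1)
b <- generate_cohort(cfg)
res <- run_pipeline(b, output_dir = tempfile("audit-"))
res$rates
res$trends
res$sites$inappropriate_low$range
subset(res$models, status == "fitted")[, 1:4]
```

## Known limitations

* The bundled code map is a synthetic stand-in; real audits must supply
  their own ICD lists (Elixhauser's published list overlaps the
  stroke-risk conditions, whereas the synthetic default keeps the two
  classes disjoint so generated marginals can be controlled
  independently).
* Concomitant interacting medications (e.g. P-gp/CYP3A4 inhibitors),
  which can legitimately justify dose reduction, are not modelled.
* Medicare-linkage completeness checks and clinical-outcome analyses are
  out of scope.
* The predictor models assume one record per patient at index; dose
  changes after the first classification are only examined through the
  switch analysis.
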