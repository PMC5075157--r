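---
title: "Validating the IMPACT claims-based risk rule for pulmonary embolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating the IMPACT claims-based risk rule for pulmonary embolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impactpe)
```

## The problem

Patients hospitalized for acute pulmonary embolism (PE) differ widely in
their risk of dying early or suffering another complication. Clinical rules
such as PESI, sPESI and the Hestia criteria stratify that risk from vital
signs and laboratory values — data that administrative claims rarely carry.
The IMPACT rule ("In-hospital Mortality for PulmonAry embolism using Claims
daTa") fills that gap: a logistic model over age and eleven ICD-9-CM-coded
comorbidities, usable retrospectively by payers, hospitals and researchers
working from claims alone.

`impactpe` implements the rule and everything needed to validate it on a
claims database: code-set management, index-event cohort construction,
comorbidity ascertainment, scoring, endpoint ascertainment, and
prognostic-accuracy evaluation. Because real claims databases are
proprietary, the package also ships a synthetic claims generator with full
ground truth, so the entire pipeline is exercised and checked in a closed
loop without any data access.

## The model

The predicted absolute risk of early all-cause in-hospital death is

$$\hat p = \frac{1}{1 + e^{-x}}, \qquad
x = -5.833 + 0.026\,\mathrm{age} + \sum_{j=1}^{11} \beta_j\, z_j,$$

where the $z_j$ are indicators for myocardial infarction, chronic lung
disease, stroke, prior major bleeding, atrial fibrillation, cognitive
impairment, heart failure, renal failure, liver disease, coagulopathy and
cancer, with published log-odds weights (0.298–1.068; cognitive impairment
and cancer weigh the most). Members with $\hat p \le 1.5\,\%$ are classified
low-risk; the threshold is *inclusive*, so a risk of exactly 0.015 is low. A
comorbidity-free patient crosses the threshold between ages 63 and 64
(solving $\mathrm{logit}(0.015) = -5.833 + 0.026a$ gives $a \approx 63.4$).

Coefficients are data, not code: `impact_coefficients()` reads them from a
JSON file (the packaged default carries the published values), so
recalibrated variants load without code changes. Age enters as completed
whole years — the claims convention, and the model is linear in age so the
choice only shifts risks by at most one year's worth of log-odds; it is
pinned by tests.

## Cohort and ascertainment rules

An inpatient claim qualifies as an index PE hospitalization when PE
(ICD-9-CM 415.1x) is the primary diagnosis, or a secondary diagnosis
accompanied by a primary PE-complication code (respiratory failure 518.81,
cardiogenic shock 785.51, cardiac arrest 427.5, secondary pulmonary
hypertension 416.8, syncope 780.2) or a complication procedure
(thrombolysis 99.10, intubation 96.04/96.05, mechanical ventilation
96.70–96.72). Procedures carry no "primary position" in the diagnosis sense,
so a qualifying procedure is accepted anywhere on the claim. When several
admissions qualify, the earliest is the index event — the standard
index-event convention.

Inclusion requires age ≥ 18 at admission, continuous enrollment for the six
calendar months before admission and three months after discharge — waived
from the date of death for members who die inside the post window — and a
community (non-transfer) admission, since a transferred patient's initial
risk assessment happened elsewhere. Month arithmetic is calendar-based
(same day-of-month, clamped to month end), the claims-enrollment
convention; both window lengths are arguments. Coverage is strict by
default (`allowable_gap_days = 0`) because the inclusion criterion says
*continuous*; a bridgeable-gap option (30–45 days is common claims
practice) is provided but off by default. Each excluded candidate's ledger
entry records the *first* failed criterion in the fixed order not_adult,
insufficient_pre_coverage, insufficient_post_coverage, transfer.

Comorbidities are ascertained from any claim dated between six months
before admission and the index discharge, index claims included; both knobs
(`lookback_months`, `include_index_claims`) are exposed because derivation
conventions differ on whether the index admission's own codes count. Code
sets ship as an editable JSON registry with per-set provenance. The five
predictors outside the AHRQ 29-comorbidity schema (myocardial infarction,
stroke, prior major bleeding, atrial fibrillation, cognitive impairment)
use widely applied claims definitions; sites with bespoke lists can swap
any set via `write_registry()`/`load_registry()` without touching code.
Diagnosis and procedure codes are distinct ICD-9-CM namespaces and never
share a set, so procedure 99.10 can never collide with a 99.x diagnosis.

## Endpoints

* **In-hospital death**: discharge status `expired` *or* a death-file date
  inside the stay — either source suffices, as each is independently
  incomplete.
* **30-day death**: death on or before admission day + 30 (inclusive).
  The admission anchor follows the 30-days-of-admission convention; note an
  in-hospital death on day 35 of a long stay counts for the in-hospital
  endpoint but not the 30-day one, which is why the two 2×2 panels differ
  in both margins.
* **30-day rehospitalization**: a new all-cause inpatient claim admitted
  strictly after the index discharge and within the window.
* **30-day recurrent VTE**: a PE or DVT code on an emergency-department or
  inpatient claim (outpatient claims never qualify) admitted strictly after
  index discharge — recurrence requires a new encounter — within the
  window. The window anchor is the admission date by default, parallel to
  rehospitalization; a discharge anchor is available because "within 30
  days of the index event" is genuinely ambiguous.
* **Evaluability**: members not discharged within 30 days have no
  post-discharge window, so rehospitalization and recurrent VTE are
  not-evaluable (`NA`) for them. They contribute to the **composite**
  (death, rehospitalization or recurrent VTE) through death only. This
  accounting keeps every cohort member in the composite denominator, which
  is how the published panels sum to the full cohort.

## Evaluation

Orientation is fixed: a *positive* prediction is the high-risk class, so
sensitivity is the share of members with the event who were called
high-risk. Sensitivity, specificity, PPV and NPV come with Wilson score
intervals by default — the Wilson interval reproduces the published
confidence limits where the Wald interval does not, and behaves properly
near 0 and 1; Wald and exact (Clopper–Pearson) are selectable. Zero
denominators raise an explicit undefined-metric error rather than returning
a silent zero.

The AUC uses the Mann–Whitney rank estimator on the *continuous* predicted
risk (ties counted one half), with a DeLong placement-value variance for
the interval. The binary low/high classification alone bounds the AUC at
$(\mathrm{sens} + \mathrm{spec})/2$, which is well below published
continuous-score AUCs — a useful sanity check that published values cannot
be reproduced from 2×2 counts, only from patient-level risks. The estimator
is verified against an $O(n^2)$ all-pairs oracle and against `pROC`.

`calibration_by_stratum()` bins members by predicted risk (decile cut
points by default) and reports observed event proportions with Wilson
bounds — the pattern a calibrated rule shows as observed risk rising with
predicted risk. `describe_cohort()` produces the baseline table (Welch t
for means, chi-square for proportions).

The packaged reference counts (`reference_validation_counts()`) carry the
2×2 panels of a published 47,531-member external validation, so the full
metric layer can be exercised — and its arithmetic checked against the
published table — without any simulation: see `metrics_from_counts()`.

## The synthetic generator

`simulate_population()` emulates the structure the pipeline assumes, with
defaults set to the published validation cohort's margins: age truncated
normal 67.1 ± 15.0 years on [18, 100] (only mean ± SD are published);
comorbidity prevalences from the published baseline table (chronic lung
disease 34.2 %, heart failure 23.1 %, atrial fibrillation 16.4 %, cancer
15.3 %, …), sampled independently because only marginal prevalences are
published — a shared log-odds age association is available but defaults to
0. In-hospital death is sampled from the rule itself:
$\Pr(\text{death}) = \mathrm{logistic}(s \cdot x)$ with
`calibration_scale` $s = 1$ by default, making the population calibrated
to the rule *by construction* and enabling parameter-recovery tests.
Length of stay is discretized log-normal with class medians 4 (low) and 5
(high) days and log-SDs 0.55/0.70, chosen to put the quartiles near the
published 2–6 and 3–9 day ranges. Post-discharge death, rehospitalization
and recurrent-VTE probabilities per class default to values matching the
published margins (e.g. the 30-day mortality panel exceeding the
in-hospital one by ~1.5 % of members). Five percent of members are planted
as transfers and five percent with a 30-day enrollment gap inside the
baseline window; ten percent of index claims code PE in the secondary
position (of which 30 % qualify via a procedure code rather than a
complication diagnosis). One index event per member.

Every planted comorbidity becomes one baseline outpatient claim whose code
is verified at generation time to match *only* that comorbidity's set, so
ascertainment can be checked for exact agreement. A recurrent-VTE event
managed as an inpatient stay is recorded in ground truth as a
rehospitalization too — it is one by definition. The ground-truth table
carries every latent flag, the linear predictor, sampled outcomes and the
planted exclusions.

What the generator does **not** emulate: coding error and omission (codes
are planted perfectly), correlated comorbidity structure, multiple index
events, seasonal or secular trends, transfers with overlapping prior
stays, and deaths missed by the death file. Passing closed-loop tests
therefore demonstrates that the pipeline's logic is faithful to its
definitions — not that the rule would achieve any particular accuracy on
real claims, where ascertainment noise is substantial.

## Numerical choices and degenerate inputs

Inclusive boundaries throughout (day-30 death counts; risk exactly 0.015
is low). Code normalization (dot-stripping, case-folding) is idempotent;
dash ranges must have equal-width all-digit endpoints and reject reversed
ranges. `two_by_two()` is permutation-invariant. The Wilson interval is
clamped to [0, 1]; at 0/n the lower bound is 0. AUC requires at least one
event and one non-event, and ties contribute one half. Decile edges with
duplicated quantiles collapse to fewer strata; constant risks give a
single stratum. Empty claim sets yield all-false profiles, not errors; an
empty risk class is marked in the baseline table, not dropped. The CSV
round-trip writes numerics at 17 significant digits so
`write_tables()`/`read_tables()` is lossless.

## Problem sizes

The test suite exercises unit fixtures of a handful of members, module
closed loops at 2,000–20,000 members, and one full 100,000-member
closed-loop validation (the scale at which per-decile calibration checks
are meaningful); the whole suite runs in well under a minute. On the
100,000-member population the pipeline recovers planted comorbidity
flags, endpoint indicators and exclusions with 100 % agreement. Note that
requiring all ten risk deciles simultaneously within ±2 binomial SEs is a
joint test with pass probability ≈ $0.95^{10} \approx 0.60$ even for a
perfectly calibrated generator; single seeds can and do show one or two
deciles marginally outside, which is sampling noise, not miscalibration.

## A worked example

```{r example, eval = FALSE}
library(impactpe)

# accuracy arithmetic on the packaged reference panels — no simulation
m <- metrics_from_counts(reference_validation_counts())
print(m$in_hospital_death)

# full synthetic pipeline
res <- run_pipeline(run_config(tempdir(), sim = sim_config(n_members = 20000,
                                                           seed = 1)))
print(res$metrics$in_hospital_death)
head(res$calibration)
```

## Known limitations

The default comorbidity code lists are editable stand-ins drawn from the
AHRQ schema and widely used claims definitions; the original rule's exact
bespoke lists for the five non-AHRQ predictors are not redistributable
here, so sites validating against a specific database should load their
own registry. Published continuous-score AUCs cannot be reproduced from
printed counts and are out of scope. The generator's independence
assumptions make its populations cleaner than real claims; closed-loop
agreement is a logic check, not a field-performance estimate.
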