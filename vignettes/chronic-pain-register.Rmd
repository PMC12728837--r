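---
title: "Building a chronic-pain register from coded primary-care records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a chronic-pain register from coded primary-care records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpregister)
```

## The problem

Chronic pain (CP) — pain persisting beyond three months — has no agreed
diagnostic threshold in primary-care coding, is absent from incentivised
disease-register schemes, and is therefore systematically under-recorded.
Medication-only case definitions (repeat analgesic prescribing) miss
patients who manage pain without drugs; diagnosis-only definitions miss
patients whose painful condition is never coded. `cpregister` implements a
tiered register that combines both routes, together with the analyses such
a register supports: prevalence comparisons against comparator long-term
conditions (LTCs), consultation rates, consultation costing, and
logistic-regression modelling of demographic inequalities in register
membership.

## The register rule

A patient enters the CP register if either criterion (or both) holds at the
extraction date:

* **Medication criterion.** At least **4** prescription-only analgesic
  prescriptions in the previous 12 months. Tricyclics and antiepileptics
  count as analgesics, reflecting their use for pain, *except* in patients
  who carry the alternative indication's diagnosis code (depression,
  epilepsy respectively) at any date up to extraction — the dual-indication
  exclusion. Over-the-counter analgesics and non-analgesic medications
  never count. Repeat issues of the same code on the same day collapse to
  one event, guarding against duplicated extract rows.
* **Diagnostic criterion.** A two-level hierarchy over 33 pain-associated
  conditions: a **tier-1** code (a condition strongly associated with
  chronic pain, 12 of the 33) triggers the register on its own; a
  **tier-2** code (the remaining 21) triggers only alongside at least **3**
  counted analgesic prescriptions in the same window. Cancer-pain codes
  never trigger the register.

Comparator LTC registers use the simpler convention common to long-term
condition studies: one or more codes from the condition's code set at any
date up to extraction.

Three readings of the rule were genuinely open and are fixed as follows:

* **Diagnosis lookback is lifetime**, while analgesic counting is windowed
  to 12 months. Only the prescription criterion is intrinsically a rate;
  diagnoses of chronic conditions remain informative indefinitely.
* **"Four or more" counts total issues, not distinct drugs.** Repeat
  prescribing of a single analgesic is the typical signature of chronic
  use; requiring four distinct drugs would be far stricter.
* The tier-2 threshold of three prescriptions counts the **same** events
  as the medication criterion — same window, same exclusions.

All thresholds and the entire vocabulary (medication classes, tiers,
dual-indication links, LTC code sets) are supplied by a YAML **codebook**,
parsed strictly (unknown keys are errors). The shipped codebook is a
synthetic placeholder vocabulary with the documented shape — 33 tiered
conditions (12 tier-1), 31 comparator LTCs, a complete 12-cell cost
schedule — because real SNOMED-CT/EMIS code lists are licensed artefacts
that users must substitute themselves.

## Cohort rules

Eligibility requires age ≥ 18 in completed years at extraction, a
registration interval covering the whole 12 months (read as 365 continuous
days) before extraction, and no informed-dissent flag. Each excluded
patient is counted under exactly one reason, so cohort plus exclusions
always reconciles to the input.

Deprivation uses *local* quintiles: cut-points are the 20/40/60/80
percentiles of the IMD score within the eligible cohort itself (patient
level), so the five groups are equal-sized up to ties. A score tied with a
cut-point goes to the lower (less deprived) quintile — a deterministic
convention that keeps reruns identical. Ethnicity is grouped to the
census-style levels with Black African and Black Caribbean separated, and
missing ethnicity kept as its own `unknown` level rather than dropped.

## The synthetic-EHR generator

No patient-level extract can be shipped, so validation rests on a seeded
generator whose defaults describe an inner-city, young, multi-ethnic,
deprived practice population:

* **Demographic marginals** (defaults): 54.0% White, 10.2% Black African,
  6.4% Black Caribbean, 8.1% Asian, 5.5% Mixed, 8.2% Other, 7.7% ethnicity
  unknown; language preference recorded for 75.9% (71.5% of those
  English); country of birth recorded for 54.2% (45.2% of those UK-born);
  50.8% female; a young age mixture (48% under 40) with every 10-year band
  populated from n = 10 000 or so upward. Fields are drawn independently:
  the joint distribution of real demographics is not available, and this
  is the main respect in which the generator is *less* structured than
  real data.
* **Latent CP status** follows a logistic model with planted odds ratios
  (dominant age gradient rising from 1.67 at 30–39 to 39.91 at ≥ 90;
  2.22 for female sex; 1.16–1.70 across deprivation quintiles 2–5; modest
  ethnicity effects; 0.95 for non-English preference; 0.61 for non-UK
  birth). The intercept is not a free parameter: it is calibrated by root
  finding at simulation time so that the mean model probability over the
  drawn covariates equals the target prevalence (default 18.6%).
* **Events are generated conditionally on a pathway** assigned to each
  CP-positive patient (medication-only 35%, tier-1 diagnosis 30%, tier-2
  plus three analgesics 20%, both 15% — a free choice, since no pathway
  breakdown is available to copy). Positive patients receive events
  guaranteed to satisfy their pathway's rule; negative patients receive at
  most three counted analgesics, at most two if they carry a tier-2
  "near-miss" code (10% of negatives), and never a tier-1 code. Counted
  prescriptions land on distinct days so same-day collapsing cannot erode
  a guarantee. Because of this construction the generator truth is an
  *exact* oracle: the register must recover it with sensitivity and
  specificity 1, and the tests assert exactly that.
* **Dual-indication traffic**: carriers of epilepsy (and, less often,
  depression) codes also receive antiepileptic (tricyclic) prescriptions
  that the register must refuse to count; cancer-pain codes are sprinkled
  at 1% and must never trigger.
* **Consultations** are drawn per patient from a negative binomial with
  mean 15.3 for CP-positive patients and a complementary mean for the rest
  chosen to hit an overall mean of 6.7 per patient-year. Only these two
  means are pinned; comparator-LTC-specific consultation means are not
  modelled, so LTC rate contrasts in synthetic runs are flatter than in
  real data. Dispersion (size 1.5) is a documented free choice — only
  means are available to match, and primary-care contact counts are
  strongly overdispersed. Provider/mode cells follow a GP-heavy mix
  (74% GP) and durations are recorded for 70% of events.
* **Missingness** is completely at random per field, which is exactly the
  regime in which complete-case logistic regression is unbiased; real
  missingness is unlikely to be MCAR, and passing recovery tests does not
  speak to that.

Comparator-LTC codes are assigned independently of CP status with
configurable prevalences (anxiety 21.4% at the top). Real comorbidity is
correlated with pain; this independence is a deliberate simplification, so
synthetic runs understate, for example, consultation rates of registers
that overlap CP.

## Utilisation and costing

Rates count *every* consultation of register members in the window —
overall utilisation, not pain-specific contacts, since consultation-level
problem codes are unreliable. Costs attach the provider-by-mode cell cost
(per-minute staff rate × mean duration for that cell; placeholder values
in the shipped schedule) to each event. A flag switches to costing each
event's own recorded duration where present; the default uses cell means,
the convention implied by duration-adjusted national unit costs.

Numerical conventions: all cost accumulation is in integer pence (so
provider components sum to totals bit-exactly, and doubling every rate
exactly doubles every output), converted to GBP only at output; rates are
reported to 1 decimal place, per-patient costs to the nearest pound, the
excess-cost headline to the nearest integer percent; all reporting uses
round-half-away-from-zero, not banker's rounding. Ranking of conditions is
a stable descending sort with alphabetical tie-break.

## Inequalities model

CP register membership is regressed on age band (reference 18–29), sex
(male), local IMD quintile (1), grouped ethnicity (White, with `unknown`
retained as a level), language preference (English) and country of birth
(UK) via maximum-likelihood logistic regression (IRLS, convergence
tolerance 1e-10, up to 100 iterations). Results are adjusted odds ratios
with 95% Wald intervals, `exp(coef ± 1.959964 × SE)`, from
observed-information standard errors; no multiple-testing adjustment.

Missing policy mirrors reporting practice: ethnicity missing becomes the
`unknown` level (which receives its own odds ratio); language, country and
IMD are complete-case, with dropped counts surfaced in a missingness
report rather than silently resolved — under the default marginals roughly
59% of rows drop, dominated by country-of-birth completeness of 54%, and
the report makes that cost visible. Aliased (perfectly collinear) columns,
apparent separation (|coefficient| > 15), and non-convergence are all hard
errors; penalised fits are out of scope.

## Validation strategy and problem sizes

The test suite validates each layer against an independent route, at sizes
chosen to keep the full suite in the low minutes:

* register vs a deliberately naive per-patient brute-force evaluation of
  the rules: exact equality over 100 seeded bundles of 500 patients;
* register vs generator truth: sensitivity = specificity = 1 at n = 2 000
  and 10 000;
* planted-parameter recovery: 50 replicates at n = 50 000; each planted
  odds ratio must fall inside the fitted 95% interval in at least 90% of
  replicates;
* preset calibration at n = 100 000: register prevalence within 3
  Monte-Carlo standard errors of 18.6%, CP consultation mean within 2
  standard errors of 15.3;
* univariable fits against the closed-form cross-product odds ratio, and
  type-I calibration under a planted null;
* exact cost conservation on every run.

`scripts/acceptance.R` reruns the whole pipeline at n = 200 000 from a
single seed and reports the headline quantities it computes.

## Limitations

The generator emulates marginal structure, planted conditional effects,
and rule-consistent event streams — not clinical reality: no correlated
comorbidity, no joint demographic structure, no informative missingness,
no multi-year trajectories, no miscoding. Passing its oracle tests
demonstrates that the algorithm implements the stated rules exactly and
that the inference layer recovers known signals; it cannot validate the
rules themselves against clinical ground truth. The shipped codebook and
cost schedule are placeholders; substantive use requires real code lists
and current unit costs. Costing covers primary-care consultations only —
no medication, secondary-care or social-care costs.
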