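# cpregister

Chronic pain (CP) is one of the most common long-term conditions managed in
primary care, yet it has no incentivised disease register and no consensus
coding threshold, so it is invisible in most register-based analyses.
`cpregister` is an R package for epidemiologists and health-service
researchers working with coded primary-care extracts (prescription,
diagnosis and consultation event tables). It builds a CP register from a
tiered case definition, compares it against comparator long-term-condition
(LTC) registers, and quantifies the utilisation, cost, and demographic
inequality consequences.

## The register definition

A patient aged ≥ 18 with a continuous 12-month record enters the CP
register at the extraction date *t* if either criterion holds:

* **Medication criterion:** ≥ 4 prescription-only analgesic prescriptions
  in (*t* − 365 d, *t*]. Tricyclics and antiepileptics count as analgesics
  *unless* the patient carries the alternative indication's diagnosis code
  (depression, epilepsy) at any date ≤ *t* (dual-indication exclusion).
  Same-day repeats of one code collapse to a single event.
* **Diagnostic criterion:** any **tier-1** pain-associated condition code
  at any date ≤ *t* (12 conditions strongly associated with pain, no
  analgesic requirement); or any **tier-2** code (21 less strongly
  associated conditions) together with ≥ 3 counted analgesic
  prescriptions. Cancer-pain codes never trigger.

Around the register the package provides: eligibility/exclusion logic with
within-sample IMD quintiles; consultation-rate summaries by provider and
mode; costing under a 12-cell provider × mode unit-cost schedule
(accumulated in integer pence, so components sum exactly); multivariable
logistic regression of register membership on age band, sex, deprivation
quintile, ethnicity, language preference and country of birth, reported as
adjusted odds ratios (aOR) with 95% Wald intervals; and a seeded
synthetic-EHR generator whose event streams are constructed to satisfy (or
just fail) the register rules, giving an exact ground-truth oracle for the
whole pipeline. Vocabularies are configurable through a YAML codebook; the
shipped codebook is a synthetic placeholder for licensed SNOMED-CT/EMIS
code lists.

## Worked example

```r
library(cpregister)

run_pipeline(list(n_patients = 20000, seed = 42), "demo_out")
cat(readLines("demo_out/summary.txt"), sep = "\n")
```

```
Chronic-pain register: run summary
==================================
Cohort size: 17686
Chronic-pain register prevalence: 19.0%

Top 5 conditions by prevalence (%):
  anxiety                          21.5
  chronic_pain                     19.0
  depression                       15.5
  hypertension                     12.1
  asthma                           11.9

Top 5 conditions by total annual consultations:
  chronic_pain                    50979 (mean 15.2/patient/year)
  anxiety                         25229 (mean 6.6/patient/year)
  ...
```

17 686 of the 20 000 simulated patients survive eligibility (the rest lack
a full 12-month record or carry a dissent flag). The register prevalence
(19.0%) sits at the generator's configured 18.6% up to Monte-Carlo noise;
anxiety, configured at 21.4%, ranks first by prevalence while CP dominates
consultation volume and cost, because CP-positive patients consult ~15
times a year against an overall mean of ~6.7. The fitted aOR table in
`demo_out/odds_ratio_report.csv` shows the planted dominant age gradient —
e.g. at this run size, age 60–69 vs 18–29 gives aOR 10.72 (95% CI 8.03 to
14.32), female vs male 2.21 (1.91 to 2.54) — and the missingness report
counts the rows dropped by complete-case handling of language and country
of birth.

The same stages are available as functions (`sim_config()`,
`simulate_population()`, `build_cohort()`, `build_cp_register()`,
`consultation_rate()`, `cost_summary()`, `fit_inequalities()`), and
`inst/scripts/cpregister-cli.R` wraps `simulate` and `run` for shell use.
See `vignettes/chronic-pain-register.Rmd` for the model, its assumptions,
and every numerical convention.

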