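# frailscan

Identifying frailty in adults aged 65+ from routinely collected health
data: linked primary-care electronic medical records (EMR) and provincial
administrative holdings (billing claims, hospital discharge abstracts,
drug dispensations, long-term-care episodes, vital statistics).

Frailty — the clinical syndrome of reduced strength, endurance and
physiological reserve — is usually graded with the 9-level Clinical
Frailty Scale (CFS: 1 = very fit … 9 = terminally ill), with CFS ≥ 5
marking the syndrome. Because CFS scoring requires clinical judgment, it
is impractical at population scale; `frailscan` implements the
computable case definitions that stand in for it, and everything needed
to evaluate them:

* **EMR case definition** — a boolean rule over code/keyword *atoms*
  (default: ICD-9 `290` dementia coding **OR** (vitamin ATC `A11` **AND**
  furosemide `C03CA01` prescriptions) **OR** the free-text whole-token
  keyword `"obstruction"`), evaluated over a 6-year lookback. Atoms,
  expression and lookback are configurable via a JSON rule file.
* **Administrative case definition** — frail if, during the index year,
  at least one of: (1) residence in long-term care / assisted living;
  (2) terminal-illness coding (default ICD-9 `V66.7`, ICD-10-CA `Z51.5`);
  (3) ≥ 2 *distinct* modified Edmonton Frail Scale domains with a
  qualifying event (cognition, mood, incontinence, falls/mobility,
  nutrition, polypharmacy > 5 distinct medications, functional
  dependence, social support).
* **Deterministic linkage** — exact match on personal health number
  (PHN), with keyed one-way identifier scrambling emulating the
  trusted-third-party release workflow.
* **Cohort inclusion** — aged 65+ on Jan 1 of the index year, ≥ 1 GP
  contact in the two years ending with it, and registry coverage for
  ≥ 75% of days alive in the index year.
* **Rolling-window comorbidity** — a person has a condition given one
  hospital diagnosis (ICD-10-CA) or two physician claims (ICD-9) within
  730 days (365 for depression, which additionally needs index-year
  treatment evidence to persist).
* **Descriptives** — the four mutually exclusive groups (frail in EMR
  only / admin only / both / neither), index-year characteristics and
  next-year utilization, costs, polypharmacy and mortality.
* **CHAID learner** — chi-square automatic interaction detection with
  stepwise category merging, Bonferroni-adjusted split selection
  (Stirling-number multiplier), bootstrap out-of-bag complexity
  selection, and stratified k-fold cross-validated sensitivity /
  specificity / PPV / NPV with exact Clopper–Pearson intervals.
* **Synthetic cohort generator** — paired EMR/admin bundles driven by a
  latent CFS-like 1–9 continuum, so the whole pipeline is testable
  without access to real health data.

## Worked example

```r
library(frailscan)

cfg    <- sim_config(n_persons = 2000, seed = 42)
gen    <- generate_cohort(cfg)            # $emr, $admin, $truth
cw     <- link_deterministic(gen$emr, gen$admin)
cw
#> <frail_crosswalk> 1940 links, linkage rate 0.970
#>   unlinked: 60 EMR, 60 administrative

cohort <- build_cohort(gen$emr, gen$admin, cw, 2014)
table(cohort$exclusion_reason)
#>            none      not_linked        under_65 no_recent_visit    low_coverage
#>            1918              60               0               0              22

emr_calls   <- apply_emr_definition(default_emr_definition(), gen$emr, cohort, 2014)
admin_calls <- apply_admin_definition(gen$admin, cohort, 2014)
groups      <- assign_groups(emr_calls, admin_calls)
table(groups$group)
#>   emr_only admin_only       both    neither
#>         94        337         83       1404
```

The linkage rate reproduces the generator's 3% unlinked default; the 22
low-coverage exclusions are persons registered for under 75% of their
days alive in 2014. The group table shows the typical asymmetry of the
two definitions: the administrative rules (driven by long-term-care
residence and multi-domain deficits) capture far more people than the
EMR screening rule, with partial overlap.

Validity metrics come with exact intervals:

```r
validity_metrics(tp = 42, fp = 43, tn = 682, fn = 108)
#> <validity_report> (95% exact CIs)
#>   sensitivity  0.280 (0.210-0.359)
#>   specificity  0.941 (0.921-0.957)
#>   ppv          0.494 (0.384-0.605)
#>   npv          0.863 (0.837-0.886)
```

This confusion matrix corresponds to a chart-review reference set of 875
patients of whom 150 were judged frail: the EMR screening definition is
highly specific but insensitive — it flags fewer than a third of truly
frail patients, which is why the administrative rules matter.

An end-to-end run (`run_pipeline(pipeline_config("out", n_persons = 5000,
seed = 1))`) writes every stage's table plus a manifest, byte-identically
for a fixed seed; `inst/scripts/frailscan.R` wraps it for the shell.

## CSV schemas

Each data source is a directory of six CSVs (ISO-8601 dates, UTF-8, LF,
empty string for absent optional values). One example row each:

| file | columns | example |
|---|---|---|
| `persons.csv` | person_id, phn, birth_date, sex, death_date, income_quintile, postal_code, coverage | `P000001,900000001,1941-03-02,female,,4,V6T2B5,2009-01-01..2015-12-31` |
| `claims.csv` | person_id, service_date, icd9_code, free_text, provider_type, fee | `P000001,2014-02-11,401.1,,gp,31.50` |
| `hospitals.csv` | person_id, admit_date, discharge_date, icd10_codes, cost | `P000001,2014-05-03,2014-05-11,I10;F03,8123.40` |
| `prescriptions.csv` | person_id, dispense_date, atc_code, source, cost | `P000001,2014-03-20,C03CA01,emr,14.25` |
| `ltc.csv` | person_id, start_date, end_date, setting | `P000001,2014-06-01,,long_term_care` |
| `observations.csv` | person_id, obs_date, kind, value | `P000001,2014-01-15,systolic_bp,128` |

`coverage` holds `;`-separated closed registry episodes
(`start..end`); `icd10_codes` holds `;`-separated diagnoses. Multi-line
rule defaults live in `inst/extdata/` (`emr_frailty_rules.json`,
`admin_frailty_rules.yaml`, `condition_defs.yaml`) and are all
overridable.

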