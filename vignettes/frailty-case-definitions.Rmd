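---
title: "Methods: frailty case definitions over linked EMR and administrative data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frailty case definitions over linked EMR and administrative data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailscan)
```

## The problem

Frailty is a clinical syndrome — diminished strength, endurance and
physiological reserve, with heightened vulnerability to falls, delirium,
institutionalization and death. The accepted bedside instrument, the
Clinical Frailty Scale (CFS), grades it 1 (very fit) to 9 (terminally
ill) by clinical judgment, with scores of 5+ defining the syndrome. No
routinely collected data element records the CFS, so population-scale
work needs *case definitions*: computable rules over diagnosis codes,
medications, free text and facility records that approximate the
clinical judgment. This package implements two such definitions — one
for primary-care EMR extracts, one for provincial administrative
holdings — together with the linkage, cohort, comorbidity and
descriptive machinery needed to compare the populations each captures,
and a CHAID learner for deriving new definitions from a labeled
reference set.

Because the real linked data sit behind provincial privacy governance,
the package ships a synthetic-cohort generator whose outputs exercise
every code path. Everything the analysis computes on real extracts it
also computes on generated data, which is how the test suite and the
acceptance script validate the implementation.

## The two case definitions

**EMR definition.** A boolean expression over named atoms, each an
`icd9_prefix`, `atc_prefix` or `text_keyword` predicate, evaluated over
a lookback window of `lookback_years` (default 6) calendar years ending
December 31 of the index year. The long window reflects how sparsely
functional deficits are coded in primary care: a dementia code or a
loop-diuretic prescription may appear years before the index year.
Matching rules worth stating precisely:

* ICD-9 prefixes match dot-insensitively (`"290"` matches `290.0` and
  `2901`), since billing extracts are inconsistent about decimal points.
* Keywords match whole tokens, case-insensitively. `"obstruction"` must
  not fire on `"obstructive sleep apnea"`: substring matching would
  conflate a marker of bowel obstruction in the very old with a common
  mid-life sleep disorder.
* The shipped default expression —
  `dementia OR (vitamins AND furosemide) OR obstruction-keyword` — is a
  documented reconstruction: the validated screening rule's published
  description names its ingredients (ICD-9 290; vitamin and/or
  furosemide prescriptions; the "obstruction" keyword) but not its exact
  boolean structure, so the expression ships in an editable JSON rule
  file and every analysis treats it as configuration, not truth.

**Administrative definition.** Frail if any of three rules fires in the
index calendar year: long-term-care or assisted-living residence
(≥ 1 day of episode overlap); terminal-illness coding (default ICD-9
`V66.7`, ICD-10-CA `Z51.5` — palliative care); or at least
`efs_min_indices` (default 2) *distinct* domains of the modified
Edmonton Frail Scale with a qualifying event. Repeated events within a
domain count once — two falls claims are one deficit, a falls claim
plus a cognition code are two. The polypharmacy domain fires on more
than 5 distinct full ATC codes dispensed in the year, the same
threshold the descriptive tables use. The domain code sets are
conservative stand-ins shipped as YAML (the operational sets used with
real provincial data are not public) and are expected to be replaced
per jurisdiction.

The two definitions deliberately look at different segments of the
frailty continuum: the administrative rules mostly detect severe,
institutionalized or end-of-life frailty, while the EMR rule screens
community-dwelling patients earlier on the continuum. The descriptive
module therefore reports the four mutually exclusive groups (EMR only,
admin only, both, neither) rather than a single prevalence.

## Cohort, linkage and comorbidity rules

*Linkage* is deterministic: exact match on personal health number, no
fuzzy fallback, duplicate PHNs within a source are an error rather than
a guess. The released files carry keyed one-way scrambled identifiers
(a salted 64-bit FNV-style hash of the PHN, implemented in the package);
the same PHN and salt always map to the same identifier, and the PHN is
dropped from released bundles. The linkage rate is reported with the
EMR person count as denominator, since the study cohort is drawn from
EMR patients; the admin denominator is available as an option.

*Inclusion* requires: linked; aged 65+ in completed years on January 1
of the index year; at least one GP (not specialist) EMR contact in the
two calendar years ending with the index year; and registry coverage
for at least 75% of days alive in the index year. Coverage uses actual
day counts on closed intervals (leap years count 366), and the
threshold is strict as stated — a person covered exactly 75% of days
alive is retained. Exclusions are labeled with the first failing rule
in the order above, which can only relabel, never change, membership.

*Comorbidity* classification uses the rolling-window rule: one hospital
diagnosis, or two physician claims at most `window_days` apart (730 by
default, 365 for depression). "Rolling two-year period" is implemented
as a 730-day difference rather than calendar anniversaries: the
calendar reading depends on leap-year placement and never differs by
more than a day. Two same-day claims count as a pair (claims are
distinct billing events); this is a documented choice suitable for
sensitivity analysis. Depression adds a persistence requirement: if the
person first qualified before the index year, some treatment evidence —
an antidepressant (ATC `N06A`) dispensation, a depression claim, or a
depression hospitalization — must appear in the index year, reflecting
the waxing/waning course of the condition.

## The synthetic-cohort generator

The generator is the package's stand-in for the study conditions, not a
tuning knob. Its defaults are fixed to the quantities the analysis
design states, and the tests measure against those defaults:

* **Latent frailty**: an ordinal-logistic CFS with age and sex effects
  (older and female shift toward frailty) and fixed cut points; the
  intercept is calibrated by root-finding so the expected fraction with
  score ≥ 5 equals `frail_fraction_target` (default 0.15, slightly
  above the ~13% combined identified-frail fraction, since no case
  definition is fully sensitive). An unreachable target raises a
  calibration error rather than silently drifting.
* **Primary-care contact volume**: negative binomial with means 20
  (frail) and 10 (non-frail) contacts per year — the two-to-one contrast
  the descriptive analysis reports — with dispersion 4.
* **Linkage**: 3% of EMR persons carry PHNs absent from the
  administrative source (emulating a 97% deterministic linkage rate),
  and an equal number of admin-only persons exists.
* **Mortality**: death in the year after the index year is logistic in
  `latent_cfs - 5` (intercept −3.0, slope 0.6), giving ~30% mortality
  at CFS 9 and under 1% at CFS 1–2, monotone by construction; half-rate
  deaths also occur within the index year so that the utilization
  denominators genuinely shrink.
* **Code emission**: each frailty atom, Edmonton domain and chronic
  condition fires per person with a class-conditional probability
  (e.g. dementia coding 0.20 vs 0.03), then emits dated, coded events.
  Costs are gamma-distributed with class-dependent means; no fee
  schedule is modeled. Atom emissions are treated as guarantees — their
  event dates clamp to the death date instead of being censored — so
  planted emission probabilities are exact in the record.

`plant_rule()` overrides emission for a chosen conjunction of atoms so
that frail persons satisfy it with stated high probability and
non-frail with stated low probability, *with dependent atom emission*:
when the conjunction does not fire, one randomly chosen atom is
suppressed and the rest still fire. This keeps each atom's marginal
uninformative on its own, so recovering the rule genuinely requires the
learner to find the interaction at the planted depth — with independent
per-atom emission, either atom alone would separate the classes and a
depth-1 tree would suffice.

What the generator does **not** emulate: realistic ICD code frequency
distributions beyond the atoms the rules use; correlation between
frailty and income or rurality (no published joint distribution is
strong enough to calibrate against, so associations are absent by
default); EMR/administrative discordance in blood-pressure capture;
lab and imaging claims (so the "other spending" cost category of real
fee data has no simulated counterpart); and out-of-province migration.
Passing tests therefore demonstrate correctness of the *rules and
machinery*, not validity of any definition on real data.

## The CHAID learner

At each node, for each categorical feature, category groups are merged
stepwise: the pair with the largest pairwise chi-square p-value merges
while that p-value exceeds `alpha_merge` (default 0.05) and more than
two groups remain. The merged feature's split p-value is multiplied by
a Bonferroni factor equal to the number of ways the original categories
collapse into the merged group count — the Stirling number of the
second kind S(c, r) — and the feature with the smallest adjusted
p-value splits the node if it passes `alpha_split` (default 0.05), all
children have at least `min_node_size` rows (default 25), and depth is
below `max_depth` (default 3). Chi-square statistics are Pearson
without continuity correction throughout; a table with no variation has
statistic 0 and p 1. A constant outcome yields a root-only tree, which
is a valid result, not an error.

Complexity is selected by bootstrap out-of-bag misclassification
(common resamples across candidates for variance reduction), with ties
broken toward simpler trees — smaller depth, then larger minimum node
size — so pure-noise labels select the simplest candidate by
construction. Validity is estimated by stratified k-fold
cross-validation (default k = 10; k = n gives leave-one-out), pooling
out-of-fold predictions into a single confusion matrix. Sensitivity,
specificity, PPV and NPV carry exact Clopper–Pearson 95% intervals
(beta quantiles; a zero denominator makes the predictive value missing
with a warning rather than NaN). The printed 21.0–36.0 interval for a
28% sensitivity on 150 frail reference patients is consistent with the
exact method to within rounding, which motivated that default. A
fitted tree converts to an EMR rule file via `as_case_definition()`
(majority-frail leaves become OR-ed conjunctions of their path
conditions).

The learner's feature space here is binary presence atoms (code family
observed in the lookback window). The operational derivation this
mirrors screened thousands of raw features; at package scale the
standard atom set (the four EMR-definition ingredients plus the eight
condition code families) exercises the same algorithmic machinery.

## Numerical and reporting conventions

* Percentages and means/SDs report to one decimal using
  round-half-away-from-zero (`table_pct()`), matching how published
  health-services tables round; base R's banker's rounding would
  disagree on exact halves.
* Blood pressure per person is the mean of the up-to-3 most recent
  readings in the index year and the year before, with a stable sort
  (date, then input order) so ties are deterministic.
* Income dichotomizes quintiles 3–5 vs 1–2; rurality is the forward
  sortation area's second character equal to `0` (the rule validates
  only the six-character shape and that second character, since that is
  all it needs; full postal-code validation happens at bundle
  construction).
* Group comparisons use Pearson chi-square without Yates correction for
  categorical blocks and Welch's unequal-variance t-test for continuous
  ones (the robust default when only "t-test" is specified); equal
  constant samples degrade to p = 1 with a warning; expected cells
  below 1 flag a small-sample warning.
* Utilization denominators for the outcome year exclude persons who
  died during the index year; hospitalization counts report per 100
  persons.
* All randomness flows from a single integer seed; the full pipeline is
  byte-identical across runs with one seed (no timestamps in any
  artifact).

## Problem sizes

The test suite and acceptance script use: 20,000 persons for generator
calibration checks (frail-fraction tolerance ±0.02, contact-ratio band
1.8–2.2), 10,000 for linkage-rate and planted-rule recovery (70/30
train/holdout), 5,000 for pipeline determinism, and 1,000-stream /
1,000-person oracle-equivalence sweeps. These sizes put Monte-Carlo
noise well inside each tolerance while keeping a full run on one core
in the tens of seconds.

## Known limitations

The shipped code sets (Edmonton domains, terminal illness, condition
prefixes) are documented stand-ins for jurisdiction-specific sets that
are not public; analyses on real data must supply their own. The EMR
definition's boolean structure is a reconstruction from its published
ingredient list. Costs are simulated aggregates with no fee schedule.
The rurality rule is the postal-code FSA convention for both simulated
provinces, though one province's operational analysis used a
statistical-area classification requiring an external lookup. And the
generator's independence assumptions (conditional on the latent class)
understate the correlation structure of real utilization data.
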