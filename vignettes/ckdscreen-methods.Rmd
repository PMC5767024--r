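---
title: "ckdscreen: models, decision rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ckdscreen: models, decision rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdscreen)
```

# The screening problem

Chronic kidney disease is usually asymptomatic until late stages, when
dialysis or transplantation is already needed. Screening is cheap — a serum
creatinine, a urinary albumin-to-creatinine ratio, age, weight, sex — yet
in many primary-care settings no nephrologist is available to interpret the
results. `ckdscreen` implements the interpretation as explicit, testable
decision rules: estimate kidney function, classify proteinuria and CKD
stage, stratify risk on the KDIGO grid, and produce a referral narrative.
It also implements the agreement statistics with which such a decision tool
is evaluated against expert raters, and a synthetic generator so the whole
pipeline is testable without patient data.

# Renal function estimation

Creatinine clearance is estimated with the Cockcroft–Gault equation,
$C = (140 - I)\,K / (72\,P)$, multiplied by 0.85 for women ($I$ age in
years, $K$ weight in kg, $P$ plasmatic creatinine in mg/dL). The equation
needs no race coefficient, which is the practical reason to prefer it over
MDRD-family equations in admixed populations; MDRD, CKD-EPI and Schwartz
are deliberately out of scope. Assumptions worth keeping in mind: the
estimate is a *clearance*, biased upward at high body weight and low muscle
mass, and is restricted here to adults (age ≥ 18, enforced by
`validate_record()`) below 140 years (the equation changes sign there).

**Rounding convention.** Displayed clearances are *truncated toward zero*
at one decimal (155.774 renders as 155.7), the convention consistent with
chart-recorded values; the full-precision value is always returned
alongside. Truncation is implemented with a $10^{-6}$ guard against binary
representation error just under a decimal boundary.

# Classification rules

All thresholds live in one YAML configuration (`ckd_config()`), with these
defaults:

* **Proteinuria** (ACR, mg/g): normal $[0, 30)$, microalbuminuria
  $[30, 300)$, albuminuria $[300, \infty)$. The middle band is half-open on
  the real line so no value is unclassifiable.
* **CKD stage** (GFR, mL/min): band edges 90/60/45/30/15; boundaries belong
  to the *less severe* stage (GFR 90 is stage 1). The six half-open bands
  tile $(0, \infty)$ with no gaps or overlaps, which the test suite checks
  on a fine grid.
* **Serum biomarkers**: creatinine 0.6–1.4 mg/dL, urea 20–40 mg/dL,
  potassium 3.5–5.5 mEq/L, closed intervals (endpoints are normal).
* **Blood pressure**: above target at systolic ≥ 140 *or* diastolic ≥ 90
  mmHg (inclusive).
* **Glucose** (mg/dL): preprandial 70–130 and fasting 70–99 inclusive;
  postprandial in range strictly below 180 (`strict_high` per context in
  the configuration).

The monitoring cut-offs follow the widely used hypertension and
diabetes-care guideline values; they are configuration, not code, because
target ranges are periodically revised and may be individualized.

# Risk stratification

Risk is a total function of (stage, proteinuria category) through an
18-cell grid reconstructed from the KDIGO heat map:

| stage | normal | microalbuminuria | albuminuria |
|-------|--------|------------------|-------------|
| 1, 2  | low    | moderate         | high        |
| 3a    | moderate | high           | very high   |
| 3b    | high   | very high        | very high   |
| 4, 5  | very high | very high     | very high   |

giving cell counts {low: 2, moderate: 3, high: 4, very high: 9}. The grid
ships as data and is overridable, but `validate_risk_matrix()` rejects a
configuration that is not total or not monotone (risk must never decrease
as stage or proteinuria worsens) unless explicitly overridden with a
warning. Two properties define the workflow's correctness and are tested
directly: it always emits *exactly one* risk level for a valid input, and
`enumerate_terminal_states()` — which drives the workflow over
representative values in every band — is a bijection onto the
$6 \times 3$ grid of 18 terminal classifications.

Biomarker flags and the SAH/DM comorbidity flags annotate the narrative but
never alter the matrix risk; whether uncontrolled comorbidity should
escalate risk is a clinical question the rules deliberately do not answer.
Records missing any of creatinine, proteinuria, age, weight or gender
produce an explicit `incomplete_panel` outcome rather than a partial
evaluation — in paper-chart data proteinuria alone can be missing from the
majority of records, and silently evaluating without it would misclassify
nearly everyone leftward on the grid.

**Screening reminders.** Intervals per risk level default to
{low: 12, moderate: 12, high: 6, very high: 3} months. No authoritative
interval table exists at this granularity; the defaults follow the common
practice of annual screening for low-risk and quarterly review for
very-high-risk patients, and the only contract the code enforces (and the
tests check) is monotonicity: higher risk never waits longer.

# Agreement statistics

Cohen's kappa, $k = (p_o - p_e)/(1 - p_e)$, corrects the observed
proportion of identical ratings $p_o$ for the agreement $p_e$ expected from
the two raters' marginal label distributions. The 95% interval is the
large-sample Wald form $k \pm 1.96\,\sqrt{p_o(1-p_o)/(n(1-p_e)^2)}$, with
no bias or prevalence adjustment, and the bounds are *not* clipped to
$[-1, 1]$: near-perfect agreement at modest $n$ legitimately produces an
upper bound above 1, and clipping would hide how uninformative the interval
is. When both raters assign one identical constant label, $p_e = 1$ and
kappa is undefined; this is raised as a typed `undefined_kappa` condition,
never returned as `NaN`.

**Multi-rater combination.** There is no single canonical way to pool
kappa over more than two raters. The default `global_kappa()` is the mean
of all pairwise Cohen's kappas, chosen because it stays interpretable
rater-by-rater (the result carries the pairwise table); Fleiss' kappa is
provided as a labeled alternative (`method = "fleiss"`). The two generally
differ and neither is claimed to be "the" multi-rater kappa — reports
record which rule produced the value.

**Per-category kappa** collapses labels to category-vs-rest, computes all
pairwise kappas on the binary indicators and averages them. A pair in
which *neither* rater ever uses the category is vacuous after the collapse
(both indicator columns constantly "no", $p_e = 1$): it carries no
information about the category and is excluded from the average; if every
pair is vacuous the result is the `undefined_kappa` signal. The CI for an
averaged kappa uses the mean pairwise $p_o$ and $p_e$ in the same Wald
form — a pragmatic choice; a delta-method SE for a mean of dependent kappas
has no closed standard form.

**Interpretation scale**: ≤ 0 absence, (0, 0.20] slight, (0.20, 0.40]
fair, (0.40, 0.60] moderate, (0.60, 0.80] substantial, > 0.80 almost
perfect. The conventional published scale leaves gaps below 0.01 and at
exactly 1.0; the bands here are right-closed so every finite value gets a
label, with $k = 0$ assigned to absence (zero chance-corrected agreement
is no agreement).

An optional `merge_map` in `agreement_report()` collapses categories before
analysis (e.g. sub-stages 3a/3b into a single stage 3), since published
agreement tables sometimes rate merged stages while decision rules
distinguish them.

# Synthetic cohorts and rater panels

`generate_cohort()` emulates a comorbid screening cohort: ages uniform on
31–79 years, hypertension prevalence 94.5%, diabetes in 58.82% of the
hypertensive subjects and (by default) in all others, so every subject
carries at least one risk factor. Weight is truncated normal (75 ± 15 kg on
40–140), urea 32 ± 12 mg/dL, potassium 4.5 ± 0.6 mEq/L; creatinine is
log-normal (median 1.0 mg/dL, log-SD 0.55) and proteinuria log-normal
(median 25 mg/g, log-SD 1.6) — families chosen only so that all stages and
categories are reachable with realistic-looking skew. These are *sampling
conveniences, not epidemiological estimates*: passing tests on this cohort
shows the decision logic is correct, not that the distributions match any
population. With a `target_mix` over risk levels the generator instead
draws a matrix cell of the requested level, samples GFR and ACR inside the
cell's bands (keeping 0.05 mL/min and 0.1 mg/g clear of the edges so
rounding cannot cross a boundary) and back-solves creatinine through
Cockcroft–Gault, so generated records have their risk level by
construction — used to cover all 18 cells.

`simulate_raters()` draws each rater's column from a row-stochastic
confusion matrix around the true label. Two constructors are provided:
`confusion_adjacent(error)` spills error mass onto adjacent categories
(the near-miss pattern typical of expert disagreement on ordered scales),
and `confusion_for_kappa(kappa0, marginal)` builds the blend
$\mathrm{row}_t = a\,e_t + (1-a)\,\pi$ with $a = \sqrt{\kappa_0}$, where
$\pi$ is the true-label marginal. Under that model each rater's marginal
equals $\pi$, and for two raters
$p_o - p_e = a^2 (1 - \sum_c \pi_c^2)$, so the expected pairwise kappa is
exactly $a^2 = \kappa_0$ — a calibrated dial for parameter-recovery
studies. At $n = 60$ subjects and 500 replicates the mean estimated global
kappa recovers design values 0.3–0.9 to well within 0.05 (finite-sample
bias from empirical marginals is $O(1/n)$).

# Document exchange

Evaluations and records export to a simplified CDA-R2-like XML template
(one fixed namespace constant instead of HL7 OIDs; four sections —
medications, allergies, lab results with units, risk evaluation) that
validates against the shipped XSD. Timestamps are injected parameters, so
document bytes are deterministic for fixed inputs, and `parse(build(x))`
recovers all template fields; unknown vendor sections survive round trips
as opaque blocks. Full HL7 CDA conformance, terminology binding
(LOINC/SNOMED) and transport are out of scope; documents are files.

# Problem sizes and numerical checks in the test suite

The suite exercises: threshold classifiers against brute-force interval
oracles on $10^4$ random values; Cohen's kappa against an independent
loop-based contingency oracle on $10^3$ random matrices at $10^{-12}$
tolerance; the exactly-one-outcome property on $10^3$ random panels; a
$10^4$-resample bootstrap cross-check of the Wald width; the 500-replicate
recovery study at $n = 60$; and CDA round trips on fuzzed records. These
sizes keep the full suite under a minute while leaving Monte-Carlo error
well below the asserted tolerances.

# Known limitations

* Cockcroft–Gault only; no pediatric scope, no race/ethnicity-adjusted
  equations, no cystatin-C.
* The risk grid is a reconstruction of the KDIGO heat map; sites using a
  modified grid must supply it in configuration (monotonicity is enforced).
* Screening intervals and monitoring targets are pragmatic defaults, not
  guideline quotations; clinical deployments must review the configuration.
* The agreement module covers unweighted kappa only — no weighted kappa,
  PABAK, or ordinal agreement models.
* The synthetic cohort does not model disease progression over time,
  lab correlation structure, or measurement error.
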