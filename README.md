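# ckdscreen

Desk-scale decision core for early detection and self-monitoring of chronic
kidney disease (CKD), aimed at the screening setting where a nephrologist is
not immediately available: primary-care workers, mHealth developers and
methods researchers who need a transparent, testable implementation of the
standard CKD decision rules together with the inter-rater agreement
machinery used to evaluate such tools against expert panels.

## What it computes

**Renal function.** Creatinine clearance by the Cockcroft–Gault equation

    C = (140 − I) · K / (72 · P)        (× 0.85 for women)

with `I` age (years), `K` weight (kg), `P` plasmatic creatinine (mg/dL);
displayed values are truncated (not rounded) at one decimal. Cockcroft–Gault
is used rather than MDRD-family equations because it requires no race
parameter. Proteinuria (urinary albumin-to-creatinine ratio, mg/g) is
classified at the conventional cut-offs: normal < 30, microalbuminuria
30–299, albuminuria ≥ 300. GFR maps onto the six KDIGO stages
(1, 2, 3a, 3b, 4, 5 at the 90/60/45/30/15 mL/min band edges).

**Risk stratification.** Stage × proteinuria category is looked up in the
KDIGO 18-cell risk grid, yielding exactly one of four levels: low, moderate,
high, very high. The workflow has exactly 18 terminal classifications, which
`enumerate_terminal_states()` enumerates exhaustively. Serum biomarkers
(creatinine 0.6–1.4 mg/dL, urea 20–40 mg/dL, potassium 3.5–5.5 mEq/L) and
the SAH/DM comorbidity flags annotate the evaluation narrative without
altering the matrix risk. Every threshold lives in a YAML configuration
(`ckd_config()`), overridable per call.

**Self-monitoring.** Blood-pressure (above target at ≥ 140/90 mmHg) and
context-specific glucose classification (preprandial 70–130, postprandial
< 180, fasting 70–99 mg/dL), identical for manual and sensor-sourced
readings; medication/allergy and drug-interaction alerts; append-only JSON
evaluation histories; simplified HL7-CDA-style XML export/import of records
and evaluations (schema in `inst/extdata/cda-schema.xsd`).

**Agreement statistics.** Cohen's kappa `k = (po − pe)/(1 − pe)`, with the
large-sample Wald 95% interval `k ± 1.96·√(po(1−po)/(n(1−pe)²))`
(deliberately unclipped), per-category kappa (binary collapse, mean over
rater pairs), global multi-rater kappa (mean pairwise, or Fleiss' kappa as a
labeled alternative) and the conventional interpretation scale (slight /
fair / moderate / substantial / almost perfect). A seeded synthetic module
generates screening cohorts with known ground truth and rater panels at a
calibrated design kappa.

## Worked example

```r
library(ckdscreen)
rec <- patient_record(id = "2", gender = "female", age = 60, weight = 80,
                      sah = TRUE, dm = TRUE,
                      creatinine = 0.54, urea = 25.2, potassium = 4.1,
                      proteinuria = 0.6)
evaluate_risk(rec, time = as.POSIXct("2026-09-24 10:00:00", tz = "UTC"))
#> CKD risk evaluation for patient 2 (2026-09-24T10:00:00)
#>   GFR 139.9 mL/min -> stage 1; proteinuria: normal
#>   Risk level: low
#>   Note: creatinine low (0.54 mg/dL)
#>   Risk factors present: SAH, DM
#>   Low risk of CKD development. Maintain routine screening.
```

The clearance 139.9 is (140−60)·80/(72·0.54)·0.85 = 139.917… truncated at
one decimal; normal proteinuria (0.6 mg/g) at stage 1 is the lowest cell of
the risk grid, so the narrative recommends routine screening only. On a
panel of raters (here the six-subject sample shipped as
`inst/extdata/ratings-sample.csv`, three nephrologists plus an app column):

```r
ratings <- read_ratings(system.file("extdata", "ratings-sample.csv",
                                    package = "ckdscreen"))
cohen_kappa(ratings[, "Nephro 1"], ratings[, "App"])
#> Kappa = 0.5385 (moderate agreement), 95% CI [0.0162, 1.0607]
#>   observed agreement 0.6667, expected 0.2778, n = 6, method = cohen
```

i.e. 4 of 6 subjects rated identically (po = 2/3) against a chance
expectation pe = 10/36, giving k = 7/13 ≈ 0.5385; at n = 6 the unclipped
Wald interval legitimately crosses 1. `agreement_report(ratings)` tabulates
per-category kappas plus a global row the same way.

A command-line wrapper is installed at `inst/cli/ckdscreen.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ckdscreen.R", package="ckdscreen"))')" \
    gfr --gender F --age 60 --weight 80 --creatinine 0.54
#> 139.9
```

Subcommands: `gfr`, `evaluate`, `monitor bp|glucose`, `kappa`,
`export-cda`, `import-cda`, `simulate cohort|raters`, `enumerate`.

## Data notes

`inst/extdata/chart-sample.csv` mirrors a nephrology screening chart
(columns ID, SAH, DM, Creatinine, Urea, Microalbuminuria, Potassium,
Weight, Age, Gender, GFR; `X` marks a comorbidity, blank cells are absent
labs). Row `7` is a synthetic addition constructed to keep the fixture at
six complete-format rows; the GFR column holds the values as recorded on
the source charts. The package performs no real EHR connectivity, device
transport, or full HL7 CDA conformance — see the methods vignette
(`vignettes/ckdscreen-methods.Rmd`) for scope, assumptions and limitations.
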