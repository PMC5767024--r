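Package: ckdscreen
Title: Chronic Kidney Disease Screening, Self-Monitoring and Rater-Agreement Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Desk-scale decision core for early detection and self-monitoring of
    chronic kidney disease (CKD). Estimates creatinine clearance with the
    Cockcroft-Gault equation, classifies proteinuria, biomarkers and CKD stage,
    stratifies risk on the KDIGO stage-by-albuminuria grid, monitors blood
    pressure and glucose for hypertensive and diabetic patients, checks
    medication and allergy alerts, and exchanges evaluations as simplified
    HL7-CDA-style XML documents. Includes the multi-rater Cohen's kappa
    agreement machinery used to evaluate such decision support against expert
    raters, and a seeded synthetic cohort and rater-panel generator so every
    component is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
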