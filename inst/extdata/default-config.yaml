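# Default clinical thresholds for ckdscreen.
#
# Keys:
#   biomarkers.<name>.low / .high : closed reference interval (endpoints normal)
#   biomarkers.<name>.unit        : display unit
#   proteinuria.microalbuminuria  : lower cut-off of microalbuminuria (mg/g ACR)
#   proteinuria.albuminuria       : lower cut-off of albuminuria (mg/g ACR)
#   stage_edges                   : GFR band edges in mL/min, descending; a GFR
#                                   at or above edge[i] and below edge[i-1] is
#                                   in stage i; below the last edge is stage 5.
#                                   Boundaries belong to the less-severe stage.
#   risk_matrix.<stage>.<category>: KDIGO stage-by-albuminuria risk grid
#   screening_intervals_months    : recommended months until next screening
#   blood_pressure                : above-target thresholds (inclusive), mmHg
#   glucose.<context>.low/.high   : target interval, mg/dL; low omitted means 0,
#                                   high bound is exclusive for postprandial
#                                   style "< high" targets (strict: true)

biomarkers:
  creatinine: {low: 0.6, high: 1.4, unit: "mg/dL"}
  urea: {low: 20.0, high: 40.0, unit: "mg/dL"}
  potassium: {low: 3.5, high: 5.5, unit: "mEq/L"}

proteinuria:
  microalbuminuria: 30
  albuminuria: 300

stage_edges: [90, 60, 45, 30, 15]

risk_matrix:
  "1":  {normal: low,      microalbuminuria: moderate,  albuminuria: high}
  "2":  {normal: low,      microalbuminuria: moderate,  albuminuria: high}
  "3a": {normal: moderate, microalbuminuria: high,      albuminuria: very_high}
  "3b": {normal: high,     microalbuminuria: very_high, albuminuria: very_high}
  "4":  {normal: very_high, microalbuminuria: very_high, albuminuria: very_high}
  "5":  {normal: very_high, microalbuminuria: very_high, albuminuria: very_high}

screening_intervals_months: {low: 12, moderate: 12, high: 6, very_high: 3}

blood_pressure: {systolic: 140, diastolic: 90}

glucose:
  preprandial:  {low: 70, high: 130, strict_high: false}
  postprandial: {low: 0,  high: 180, strict_high: true}
  fasting:      {low: 70, high: 99,  strict_high: false}
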