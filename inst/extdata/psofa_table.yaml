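# Pediatric Sequential Organ Failure Assessment (pSOFA) cutoffs.
# Six organ systems, each scored 0-4; total 0-24. Encoded as a data file so
# the cutoffs are auditable and editable without touching code.
#
# Conventions used by the scorer:
#   *_lower vectors: score k (k = 1..4) when the value is BELOW bound[k]
#                    (bounds are decreasing; the score is the number of bounds
#                    the value falls below).
#   *_upper vectors: score k when the value is AT OR ABOVE bound[k]
#                    (bounds increasing).
#   Respiratory scores 3-4 additionally require respiratory support.
#   Cardiovascular and renal cutoffs are selected by age band (months,
#   half-open [min, max)).
version: 1
respiratory:
  sf_ratio_lower: [292, 264, 221, 148]   # SpO2:FiO2, used when PaO2 absent
  pf_ratio_lower: [400, 300, 200, 100]   # PaO2:FiO2
  support_required_from: 3
coagulation:
  platelets_lower: [150, 100, 50, 20]    # 10^3/uL
hepatic:
  bilirubin_upper: [1.2, 2.0, 6.0, 12.0] # mg/dL
neurologic:
  gcs_lower: [15, 13, 10, 6]             # Glasgow Coma Scale
cardiovascular:
  # MAP (mmHg) scores 0 at or above map_min for the age band, 1 below it;
  # vasoactive infusions override to scores 2-4.
  map_age_bands:
  - {min_months: 0,   max_months: 1,   map_min: 46}
  - {min_months: 1,   max_months: 12,  map_min: 55}
  - {min_months: 12,  max_months: 24,  map_min: 60}
  - {min_months: 24,  max_months: 60,  map_min: 62}
  - {min_months: 60,  max_months: 144, map_min: 65}
  - {min_months: 144, max_months: 217, map_min: 67}
  # default count-based tiers when doses are not recorded
  vasoactive_count_scores: [2, 3, 4]     # 1, 2, >=3 concurrent agents
renal:
  # creatinine (mg/dL); score k when >= lower[k]
  creatinine_age_bands:
  - {min_months: 0,   max_months: 1,   lower: [0.8, 1.0, 1.2, 1.6]}
  - {min_months: 1,   max_months: 12,  lower: [0.3, 0.5, 0.8, 1.2]}
  - {min_months: 12,  max_months: 24,  lower: [0.4, 0.6, 1.1, 1.5]}
  - {min_months: 24,  max_months: 60,  lower: [0.6, 0.9, 1.6, 2.3]}
  - {min_months: 60,  max_months: 144, lower: [0.7, 1.1, 1.8, 2.6]}
  - {min_months: 144, max_months: 217, lower: [1.0, 1.7, 2.9, 4.2]}
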