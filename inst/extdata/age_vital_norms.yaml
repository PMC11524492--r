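# Age-specific vital-sign and leukocyte bounds used by the Goldstein SIRS
# criteria: tachycardia above hr_high; bradycardia below hr_low (defined only
# for infants); tachypnoea above rr_high; abnormal leukocyte count above
# wbc_high or below wbc_low (10^3/uL). Fever/hypothermia cutoffs apply to
# core temperature at all ages. Bands are half-open [min_months, max_months).
version: 1
fever_above_c: 38.5
hypothermia_below_c: 36.0
bands:
- {min_months: 1,   max_months: 12,  hr_high: 180, hr_low: 90,   rr_high: 34, wbc_high: 17.5, wbc_low: 5.0}
- {min_months: 12,  max_months: 24,  hr_high: 180, hr_low: .na,  rr_high: 34, wbc_high: 17.5, wbc_low: 5.0}
- {min_months: 24,  max_months: 72,  hr_high: 140, hr_low: .na,  rr_high: 22, wbc_high: 15.5, wbc_low: 6.0}
- {min_months: 72,  max_months: 156, hr_high: 130, hr_low: .na,  rr_high: 18, wbc_high: 13.5, wbc_low: 4.5}
- {min_months: 156, max_months: 216, hr_high: 110, hr_low: .na,  rr_high: 14, wbc_high: 11.0, wbc_low: 4.5}
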