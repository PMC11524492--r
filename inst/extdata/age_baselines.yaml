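# Age-band resting baselines used by the synthetic cohort generator: the
# expected value of each signal for a patient of that age at latent severity
# zero. Severity effect sizes in the generator config shift these values.
# Bands are half-open [min_months, max_months). Editable.
version: 1
bands:
- {min_months: 2,   max_months: 12,  hr: 130, rr: 35, hrv: 30, skin_t: 36.4, core_t: 37.0, activity: 0.15,
   map: 65, spo2: 98, platelets: 300, bilirubin: 0.5, creatinine: 0.20, wbc: 10.0}
- {min_months: 12,  max_months: 60,  hr: 115, rr: 26, hrv: 40, skin_t: 36.4, core_t: 37.0, activity: 0.18,
   map: 70, spo2: 98, platelets: 300, bilirubin: 0.5, creatinine: 0.35, wbc: 9.0}
- {min_months: 60,  max_months: 144, hr: 95,  rr: 21, hrv: 50, skin_t: 36.3, core_t: 36.9, activity: 0.16,
   map: 75, spo2: 98, platelets: 280, bilirubin: 0.5, creatinine: 0.50, wbc: 8.0}
- {min_months: 144, max_months: 216, hr: 82,  rr: 16, hrv: 60, skin_t: 36.3, core_t: 36.9, activity: 0.14,
   map: 80, spo2: 98, platelets: 260, bilirubin: 0.6, creatinine: 0.70, wbc: 7.5}
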