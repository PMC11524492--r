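# Age-banded vital-sign thresholds in the style of the Modified Pediatric
# Early Warning Score (MPEWS). "Red" is the most abnormal ("danger") zone:
# a value at or beyond a red bound is classified red (bounds inclusive).
# normal_low/normal_high give the age-band reference range used to normalise
# "worst value" extremity. Bands are half-open [min_months, max_months) and
# must tile [2, 216) months. Editable by the user.
version: 1
bands:
- name: infant
  min_months: 2
  max_months: 12
  hr:     {red_low: 90,   red_high: 180,  normal_low: 100,  normal_high: 160}
  rr:     {red_low: 20,   red_high: 60,   normal_low: 30,   normal_high: 50}
  skin_t: {red_low: 35.0, red_high: 39.0, normal_low: 36.0, normal_high: 37.5}
  core_t: {red_low: 35.0, red_high: 39.5, normal_low: 36.5, normal_high: 38.0}
- name: toddler
  min_months: 12
  max_months: 60
  hr:     {red_low: 70,   red_high: 160,  normal_low: 90,   normal_high: 140}
  rr:     {red_low: 15,   red_high: 40,   normal_low: 20,   normal_high: 30}
  skin_t: {red_low: 35.0, red_high: 39.0, normal_low: 36.0, normal_high: 37.5}
  core_t: {red_low: 35.0, red_high: 39.5, normal_low: 36.5, normal_high: 38.0}
- name: child
  min_months: 60
  max_months: 144
  hr:     {red_low: 60,   red_high: 140,  normal_low: 80,   normal_high: 120}
  rr:     {red_low: 12,   red_high: 34,   normal_low: 16,   normal_high: 28}
  skin_t: {red_low: 35.0, red_high: 39.0, normal_low: 36.0, normal_high: 37.5}
  core_t: {red_low: 35.0, red_high: 39.5, normal_low: 36.5, normal_high: 38.0}
- name: adolescent
  min_months: 144
  max_months: 216
  hr:     {red_low: 50,   red_high: 130,  normal_low: 60,   normal_high: 100}
  rr:     {red_low: 10,   red_high: 30,   normal_low: 12,   normal_high: 20}
  skin_t: {red_low: 35.0, red_high: 39.0, normal_low: 36.0, normal_high: 37.5}
  core_t: {red_low: 35.0, red_high: 39.5, normal_low: 36.5, normal_high: 38.0}
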