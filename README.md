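# sepsiswear

Continuous wearable vital-sign monitoring can bring telemetry-grade
surveillance to pediatric intensive-care settings where laboratory testing
and specialist staffing are scarce. `sepsiswear` implements the full analysis
chain for evaluating that idea on a monitored cohort of children with
sepsis:

- **Signal quality.** Each one-minute wearable window carries a signal
  quality index (SQI, 0–100%); windows with SQI < 75% are discarded and
  per-patient capture fractions reported.
- **Severity scoring.** Twice-daily pediatric Sequential Organ Failure
  Assessment (pSOFA) scores — six organ subscores of 0–4 (respiratory via
  SpO2:FiO2, coagulation, hepatic, cardiovascular via age-adjusted MAP and
  vasoactives, neurologic via GCS, renal via age-adjusted creatinine) —
  define the outcome: *advanced sepsis* is a total > 8. Goldstein SIRS
  criteria and MPEWS "red zone" classification are computed from the same
  editable age-band YAML tables.
- **Features.** For each anchor time, the quality-filtered stream in a
  centred one-hour window is summarised per vital (HR, RR, HRV, skin and
  core temperature, activity) as mean, sample SD, and worst (most extreme
  relative to the age-band normal range), plus percent of time in the MPEWS
  red zone; manual candidates (MAP, SpO2:FiO2, demographics, exam findings)
  are carried alongside.
- **Models.** Ridge regression on the 0/1 outcome:
  `min ||y − β₀ − Xβ||² + λ||β||²` with z-scored features and an
  unpenalised intercept. Model A uses all candidates, Model B the features
  explaining ≥ 4% of outcome variation (r² screen), Model C the screened
  wearable-only features. Evaluation is 5-fold cross-validation iterated
  (1,000× by default) with patient-grouped folds, per-fold inner λ
  selection, AUC on pooled centred scores, and classification thresholds
  matched to the clinicians' documentation false-positive rate on training
  folds only.
- **Lead times.** Detection times of the cross-validated model and of
  clinician documentation are compared against the first pSOFA > 8
  (`lead = criterion time − detection time`; positive = earlier detection),
  averaged per patient across iterations, and tested with a Mann-Whitney U.
- **Agreement.** Manual observations pair with the nearest kept stream
  minute within 5 minutes; Pearson r, mean absolute error, and Bland-Altman
  limits of agreement (bias ± 1.96 SD, with a repeated-measures variance
  components SD by default) quantify manual-versus-wearable agreement.

Because no monitored pediatric sepsis cohort of this kind is public, the
package ships a first-class synthetic cohort generator: a latent severity
index in [0, 1] evolves per patient as a bounded random walk with
deterioration episodes and drives every observable (vitals, SQI dropout,
labs with ~9% missingness, MAP/GCS, lagged and sometimes spurious clinician
documentation). All downstream code is exercised and tested against this
generator's known ground truth.

## Worked example

```r
library(sepsiswear)
cfg <- pipeline_config(generator = generator_config(n_patients = 30),
                       model_iterations = 100, leadtime_iterations = 50,
                       seed = 11)
rep <- run_pipeline(cfg)
print(rep)
#> Sepsis pipeline report (seed 11, config 5c86fd24)
#>   30 patients; 147 assessments (9 missing); advanced prevalence 0.30
#>   median high-quality capture: 0.9936
#>   model A: AUC 0.879 (SD 0.053), sens 0.979, F1 0.498 [38 features]
#>   model B: AUC 0.948 (SD 0.029), sens 1.000, F1 0.548 [18 features]
#>   model C: AUC 0.928 (SD 0.037), sens 0.969, F1 0.526 [14 features]
#>   clinician: sens 0.805, spec 0.784, F1 0.695 (FPR 0.216)
#>   lead time: model 12.03 h vs clinician 4.09 h (p = 0.00708)
```

Reading the report: 30 synthetic children were monitored for ~2.2 days
each; 99.4% of wearable minutes passed the quality filter. Of 147
twice-daily pSOFA assessments, 9 were missing due to missing labs, and 30%
of the rest met the advanced-sepsis criterion. The wearable-plus-clinical
model (B) discriminated advanced sepsis with mean AUC 0.95 across 100
cross-validation repetitions; the wearable-only model (C) reached 0.93. At
a threshold matched to the clinicians' documentation false-positive rate
(0.216), the model detected advanced sepsis on average 12.0 h before the
first pSOFA > 8 versus 4.1 h for clinician documentation.

Individual stages are available as plain functions (`filter_low_quality()`,
`compute_psofa()`, `build_feature_matrix()`, `cross_validate()`,
`bland_altman()`, `first_detection_leads()`, ...) and accept user-supplied
CSVs in the documented cohort schema via `read_cohort()`.

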