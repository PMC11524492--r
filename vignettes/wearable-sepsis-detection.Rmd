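---
title: "Detecting advanced pediatric sepsis from wearable vital signs"
author: "sepsiswear authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting advanced pediatric sepsis from wearable vital signs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Children with sepsis deteriorate quickly, and in intensive-care settings
with high patient-to-clinician ratios the signs of progression — rising
heart and respiratory rates, falling blood pressure, depressed
consciousness — can be recognised late. A chest-worn wearable that streams
per-minute heart rate (HR), respiratory rate (RR), heart-rate variability
(HRV), skin and core temperature, and an accelerometer activity summary
offers continuous surveillance without laboratory tests. `sepsiswear`
implements the statistical machinery for asking whether such a stream can
discriminate *advanced sepsis* — defined throughout as a pediatric
Sequential Organ Failure Assessment (pSOFA) total strictly greater than 8
at a twice-daily assessment — and whether it can do so earlier than routine
clinician documentation.

```{r}
library(sepsiswear)
```

## The synthetic cohort and what it emulates

No cohort of this kind is publicly deposited, so the package's generator is
a first-class, tested component rather than a test fixture. Its defaults
encode the monitored-ICU conditions the analysis assumes; they were fixed
once, before the downstream results were inspected, and are not tuned
thereafter.

**Latent severity.** Each patient carries a latent severity index in
[0, 1], simulated as a bounded random walk on a 5-minute grid (reflecting
at 0, absorbing at 1) and linearly interpolated to minutes. This is the
simplest process with controllable deterioration: with probability 0.25 a
patient enters a deterioration episode — an added drift of +0.10/h starting
at a uniform random onset in the first half of monitoring — emulating the
roughly one-in-four progression to septic shock reported for this
population. Ground truth "advanced" is severity ≥ 0.6. The walk's
volatility (0.015 per √hour) keeps spontaneous crossings rare.

**Observables.** Age-band baselines (four bands: under 12 months, 12–59
months, 5–11 years, 12–17 years, shipped as editable YAML) anchor every
signal; severity shifts each observable linearly (per-unit-severity
defaults: HR +40 bpm, RR +20 breaths/min, core T +1.5 °C, MAP −20 mmHg,
GCS −7, SpO2 −8 points with FiO2 rising +0.35, platelets −230 ×10³/µL,
bilirubin +3 mg/dL, creatinine +0.8 mg/dL). These were chosen so that the
scored pSOFA total crosses 8 at severity ≈ 0.55–0.6, i.e. the organ-
dysfunction criterion and the latent truth agree, and so that roughly 20%
of twice-daily assessments are advanced — the prevalence regime the
analysis is designed for. Between-patient baseline spread (e.g. HR SD
8 bpm) makes wearable features realistically noisy labels of severity.

**Imperfections.** Monitoring lasts ~52.5 h on average (truncated normal).
SQI dropout arrives as Poisson bursts (0.1/h, mean 5 min) with SQI drawn
below 75, tuned to under 1% low-quality minutes. Manual observations equal
the stream value plus a configured bias and measurement noise (defaults
mirror small negative HR/RR offsets). Lab panels are missing with
probability 0.09, which propagates to missing pSOFA outcomes. Clinician
documentation of advanced sepsis lags true onset by a lognormal delay
(median 2 h — documentation delays are routine in busy wards), and patients
who never progress receive a spurious advanced-sepsis entry with
probability 0.25, giving documentation a realistic non-zero false-positive
rate against the criterion.

**What the generator does not emulate.** Within-patient vital-sign
autocorrelation is not calibrated to any real cohort (minutes are
conditionally independent around the severity trend); artifacts are
represented only through the SQI channel; manual temperature is modelled
from the core-temperature stream, so the skin-temperature agreement
analysis is structurally weaker than in real data; and demographics are
independent of severity. Passing tests on this cohort therefore
demonstrate the correctness and calibration of the *machinery*, not the
clinical performance to expect on real children.

## Scoring tables

All cutoffs live in editable YAML under `inst/extdata/` and are loaded, not
hard-coded:

- `psofa_table.yaml` — the published pSOFA cutoffs: six organ systems
  scored 0–4, respiratory via SpO2:FiO2 when PaO2 is absent (scores 3–4
  require respiratory support, inferred from FiO2 > 0.21 unless stated),
  cardiovascular via age-adjusted MAP with vasoactive tiers (count-based
  2/3/4 by default; dose tiers when doses are supplied), renal via
  age-adjusted creatinine. Missing labs make the assessment missing — there
  is no imputation, and such assessments are excluded from modelling.
- `mpews_thresholds.yaml` — age-banded red ("danger") zone bounds and
  normal ranges in the style of the Modified Pediatric Early Warning Score.
  Red bounds are *inclusive*: early-warning scores conventionally trigger
  at the printed threshold. The exact site-specific numbers are expected to
  be edited in; the shipped defaults follow standard pediatric banding.
- `age_vital_norms.yaml` — Goldstein SIRS bounds (tachycardia, infant
  bradycardia, tachypnoea, leukocyte count) with the fever/hypothermia
  cutoffs. `goldstein_sirs()` returns `NA` (indeterminate), never a silent
  `FALSE`, when a missing leukocyte count leaves the verdict open.

```{r}
compute_psofa(
  obs = data.frame(spo2_pct = 96, fio2_fraction = 0.48, map_mmhg = 50,
                   gcs = 12L, time_min = 0),
  labs = data.frame(platelets_10e3_ul = 120, bilirubin_mg_dl = 2.5,
                    creatinine_mg_dl = 0.2, missing = FALSE),
  profile = data.frame(patient_id = "X", age_months = 6))
```

## Feature engineering choices

Features summarise the quality-filtered stream over a *centred, half-open*
window `[anchor − 30 min, anchor + 30 min)` (width configurable): the
half-open right edge makes adjacent windows partition the stream
deterministically. Per vital the window yields mean, sample SD, and the
*worst* value; HR, RR and the two temperatures additionally yield the
fraction of minutes in the MPEWS red zone.

"Worst" is operationally ambiguous, so the package defines it as the value
maximising `|value − band midpoint| / band half-width` — extremity relative
to the age-band normal range — so that bradycardia can out-rank a mild
tachycardia in an infant. A raw-magnitude mode is available by argument.
Ties resolve to the earliest minute. Activity and HRV have no age norms;
their worst value is the largest deviation from the patient's own stream
median. Windows with zero kept minutes are flagged unusable and excluded.

## Modelling choices

**Linear ridge on the 0/1 outcome.** The detector is ridge regression used
as a linear-probability model: scores are the linear predictor, not a
logistic probability. This keeps an exact closed-form oracle available for
verification (the normal-equation solution on the standardised design) and
matches the convention of reporting ridge coefficients on z-scored
features. The fit itself uses QR on the √λ-augmented design, which is
numerically stabler than forming X'X. λ is never fixed a priori: each
training fold selects it by inner 5-fold cross-validation over a log-spaced
grid 10⁻³…10³ (mean squared error criterion), so no test information leaks
into the penalty choice.

**Feature sets.** Model A takes all candidates; Model B the features whose
squared correlation with the outcome is at least 0.04 (the threshold is
inclusive — "at least 4% of outcome variation"); Model C applies the same
screen to wearable-derived features only. Feature lists are also directly
configurable for users who want to fix them by judgment.

**Iterated grouped cross-validation.** Evaluation repeats 5-fold CV
(1,000 iterations by default; smaller in examples) with folds drawn over
*patients*, because repeated assessments of one child are strongly
correlated and record-level folds would leak identity. A record-level mode
remains available. Every iteration derives its own seed from the master
seed, so runs are exactly reproducible.

**Pooled score centring.** Per-iteration AUC is computed on the pooled
test-fold scores. Pooling raw linear predictors would embed each fold's
intercept — its training base rate — which anti-correlates with the held-out
fold's prevalence and biases the null AUC visibly below 0.5. The package
therefore pools the *centred* linear predictor (intercept removed); within
a fold this is a constant shift and changes no ranking, while across folds
it removes the base-rate artifact. With this choice the permutation-null
mean AUC sits at 0.49–0.50.

**Threshold matching.** Classification metrics are reported at a threshold
matched to the clinicians' documentation false-positive rate (measured
against the pSOFA criterion). The threshold is always computed on training
folds and applied to test folds — matching on test data would leak.
`threshold_at_fpr()` returns the smallest observed-score threshold whose
achieved FPR does not exceed the target.

## Lead-time conventions

`lead = (time of first pSOFA > 8) − (time of first detection)`, in hours;
positive means the detector fired first. Negative leads are *retained* —
flooring them at zero would bias both arms upward. Clinician detection is
the first documentation entry labelled advanced sepsis; sepsis-only entries
never count. Patients whose pSOFA never exceeds 8 contribute to neither
arm. The transition analysis (progressive sepsis) looks at assessments
with total > 8 whose immediately preceding assessment was ≤ 8 — a previous
total of exactly 8 is not advanced, so crossing from 8 counts — and takes
the first detection within the preceding inter-assessment interval.
Across the iterated train/test segmentations each patient's leads are
averaged to one value per arm before the Mann-Whitney U comparison, so
patients monitored longer do not dominate.

## Agreement conventions

Differences are always **wearable − manual**: the manual measurement by an
experienced nurse is the reference standard, and a fixed sign convention is
what makes bias values reproducible. Pairing takes the nearest kept stream
minute within 5 minutes (ties to the earlier minute). Limits of agreement
default to the repeated-measures (variance components) SD — a one-way
random-effects decomposition of the differences by patient — because many
pairs per child would otherwise narrow the limits spuriously; the pooled
SD remains available, and the two coincide exactly when every patient
contributes a single pair (the implementation collapses to pooled in that
degenerate case, and refuses partial replication below two replicated
patients rather than returning an unstable component estimate).

## Degenerate inputs and numerical edges

- An *empty* stream is an error; an all-filtered stream is a valid result
  with capture fraction 0 — the two are deliberately distinct.
- Exactly-at-threshold values: SQI 75 is kept ("fell below" removes), MPEWS
  red bounds trigger, the r² = 0.04 screen selects.
- Zero-variance features are dropped per training fold and recorded on the
  fit object; an all-constant candidate set yields an empty selection with
  a warning.
- Metric draws that are all equal to the clinician reference give t = 0,
  p = 1; zero-variance draws away from the reference are a refusal, not a
  silent zero.
- Single-minute windows report SD 0 (a point has no spread to act on);
  windows with no minutes are unusable rather than NA-filled.

## Problem sizes

The shipped tests and the acceptance script run at desk scale by design:
the generator's full study conditions (100 patients, ~52.5 h each) are used
where the quantity under test needs them, while cross-validation
repetitions are reduced (50–200 instead of 1,000) since the mean AUC
stabilises to ~0.001 well before 200 draws. The vignette and README
examples use 30 patients for speed. All sizes are arguments, and the
1,000-iteration defaults of `model_spec()` reproduce the full analysis.

## Known limitations

- The ridge detector is linear; no calibration of scores to probabilities
  is attempted, and none is needed for ranking-based AUC and FPR matching.
- Model B deliberately includes MAP and SpO2:FiO2, which are also pSOFA
  inputs; on real data this induces incorporation bias in its favour, and
  the same coupling exists in the generator. Model C is free of it.
- The manual temperature is a single (rectal or oral) measurement compared
  against both skin and core streams; skin-temperature agreement is
  therefore expected to be weak in the synthetic data.
- `goldstein_sirs()` reproduces the consensus criteria but the leukocyte
  bounds are band-wise approximations where the consensus table leaves
  gaps (12–24 months).
- Nothing here validates clinical performance on real children; the
  package's claims are about correct, reproducible computation.
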