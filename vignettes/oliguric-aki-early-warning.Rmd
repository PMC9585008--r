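---
title: "Methods: early warning of severe oliguric AKI from urine-output time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: early warning of severe oliguric AKI from urine-output time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oliguard)
```

## The problem

Acute kidney injury (AKI) in intensive care carries high mortality, and the
oliguric form — AKI meeting the KDIGO urine-output criterion — carries the
highest. Urine output is charted by nurses at irregular intervals; serum
creatinine arrives from the laboratory every half day to day. An early-warning
model that continuously scores the recent urine-output trend can flag patients
hours before the KDIGO stage 2/3 criteria are met, buying time for volume
management, nephrotoxin withdrawal and renal-replacement planning.

`oliguard` implements that analysis end to end: hourly resampling of the raw
streams, KDIGO staging and composite oliguric-AKI stage 2/3 episode
detection, cohort filtering, 12-hour sliding observation windows with a
24-hour prediction horizon, a multi-feature logistic model, a
parallel-branch 1D convolutional network, and ROC operating-point
evaluation with likelihood ratios. Because the clinical databases this kind
of study draws on are access-controlled, the package ships a synthetic
cohort generator with the statistical structure the analysis assumes, so
that every stage is exercised and tested without any data download.

## Preprocessing rules

**Hourly grid.** Hour bins are half-open intervals anchored at admission;
bin `h` covers `(h-1, h]` hours, and a record timestamped exactly on a
boundary belongs to the earlier covered bin. The grid length is the whole
number of stay hours.

**Urine output.** Nurse-charted urine records carry the volume accumulated
since the previous record. A record covering `g` whole-hour bins is split
equally across those bins when `g < 9` h; at `g >= 9` h the covered bins stay
missing and the volume is assigned to the record's own bin only — a long
silent gap is treated as unobserved rather than as imputed oliguria. The
9-hour threshold is read strictly, and both boundary behaviours are pinned
by tests. Volume is conserved exactly over every split gap.

**Creatinine.** Laboratory values land in their hour bin (last value wins
within a bin — the most recent laboratory result) and are carried forward
through at most 95 subsequent missing hours, i.e. strictly less than 4
days; bins beyond the cap and bins before the first measurement remain
missing.

**Ideal body weight.** De-identified exports often report height only as a
decade range ("170-179 cm"); the midpoint of the range enters the Devine
formula (50 kg for males, 45.5 kg for females, plus 0.9059 kg per cm above
152.4 cm), floored at 40 kg. Hourly urine output is normalised to ml/h/kg
IBW.

## KDIGO staging and the composite endpoint

The urine-output stage at hour `h` is computed from the maximal run of
consecutive oliguric hours ending at `h`: below 0.5 ml/kg/h for 6–12 h is
stage 1, for more than 12 h stage 2; below 0.3 ml/kg/h for at least 24 h,
or anuria for at least 12 h, stage 3. The quoted operators are applied
literally: "more than 12 h" means a run of 13 or more hours. Missing hours
are themselves unknown and break runs — no oliguria is assumed where none
was observed. The creatinine stage uses the standard ratio-to-baseline
table (1.5–2, 2–3, at least 3 or an absolute 4.0 mg/dL, plus the
0.3 mg/dL absolute-rise clause for stage 1), with baseline defined as the
lowest recorded value, across admissions when the patient has several.

The study endpoint — hospital-acquired oliguric AKI stage 2/3 — requires a
*simultaneous* urine-output reduction and creatinine increase. How strict
"simultaneous" should be is genuinely open, and so is the creatinine side
of the conjunction. `detect_oliguric_aki()` therefore declares an episode
at the first hour with urine-output stage 2 or higher such that the
creatinine stage reaches at least `scr_stage_floor` (default 1: any
creatinine increase) within `co_window_h` hours (default ±12) — both are
configuration parameters, and the default stage floor is deliberately the
permissive reading.

## Cohort filtering and window construction

Patients are excluded when urine output is absent or more than 30% of
hourly bins are missing, when no creatinine was ever measured, when the
stay is shorter than 24 h, or when the composite condition is already met
within the first 12 h (a proxy for community-acquired AKI, which the
analysis must not claim to predict). These four thresholds stand in for
inclusion criteria that published cohort studies delegate to their own
protocols; all are configurable, and the exclusion log accounts for every
patient exactly once.

Case trajectories are truncated 6 h before the detected onset, so every
positive training window has at least 6 h of lead time; controls contribute
their whole stay. Windows are 12 consecutive fully observed hourly urine
bins (no within-window imputation), cut at a 1-hour stride, labelled 1 when
the onset falls within the following 24 h. The stride, the deep model's
horizon and the missingness tolerance are not pinned down by the source
analyses; the package fixes stride 1 and uses the same 24-hour horizon for
both models so their scores are comparable, and documents all three as
package choices.

## The two models

The logistic model sees a deliberate reconstruction of a plausible
feature set (the original is not disclosed): min, max, mean, last value and
least-squares slope of the 12 hourly diuresis values, the in-window counts
of hours below 0.5 and 0.3 ml/kg/h, the creatinine at the window end, its
ratio to baseline, the age band as an ordinal and a male-sex indicator.
Fitting is plain maximum likelihood on standardised features (IRLS,
deviance tolerance 1e-8, at most 100 iterations). Perfect separation —
possible in small or extreme cohorts — triggers a warning and a refit with
a 1e-6 L2 penalty so the coefficients stay finite; the penalty is orders of
magnitude below any scientifically meaningful shrinkage.

The deep model reads the raw 12-value urine sequence through three parallel
1D convolution branches with kernel sizes 3, 6 and 12 — sub-half-day,
half-window and whole-window temporal patterns — each with 8 filters;
branch outputs are global-max-pooled, concatenated, passed through one
16-unit ReLU layer and a sigmoid output. This is a compact, purpose-built
network (a few hundred parameters), implemented directly in vectorised R
with full-batch Adam, class-weighted binary cross-entropy (weights inverse
to class frequency, since positive windows are a few percent of the total)
and early stopping on a patient-level validation split: windows of one
patient never appear on both sides of any split, here or in the train/test
partition. Fixed seeds make training bit-reproducible on a single CPU
thread.

## Evaluation

ROC curves are exhaustive threshold sweeps (positive when the score is at
least the threshold), so the trapezoidal AUC equals the Mann–Whitney
concordance probability with ties counted one half — an identity the test
suite checks against a brute-force pair-counting oracle. The AUC standard
error uses the Hanley–McNeil formula. Two operating points are reported:
the fixed-sensitivity point (the threshold maximising specificity among
those attaining 80% sensitivity, ties toward the higher threshold) and the
knee-point. "Knee" has no canonical definition; the package uses the
threshold closest to the ideal ROC corner in Euclidean distance, with
Youden's J available behind a flag. Likelihood ratios are
`LR+ = sens/(1-spec)` and `LR- = (1-sens)/spec`, rendered at two decimals
with halves away from zero, matching clinical-table conventions. Patient
scores aggregate windows by maximum (alert semantics — an alert fires if
any window crosses the threshold); mean aggregation is an option.

`check_reference_tables()` re-derives every published LR cell of the two
external-validation result tables from its own row's printed sensitivity
and specificity. Because the printed percentages are rounded, each cell is
checked against the exact interval implied by half-unit rounding; two
published eICU LR− cells fall outside their intervals (0.31 printed against
an implied maximum of 0.275, and 0.20 against an implied minimum of 0.231)
and are flagged as likely typesetting errors, not reproduction targets.

## What the synthetic generator emulates — and what it does not

The generator reproduces the statistical features the pipeline's logic
depends on:

* **Charting regimes.** Inter-record intervals are gamma-distributed with
  configurable medians — 1.3 h urine / 16.2 h creatinine for the
  "Amsterdam-like" dense regime, 2.4 h / 23.2 h for the "eICU-like" sparse
  regime. Creatinine draw gaps are capped at 28 h (ICUs draw chemistry at
  least about daily) and densify to a 12 h cap once oliguria begins,
  reflecting illness-driven lab intensity. A small per-record probability
  (0.003) of a 9–18 h silent urine gap exercises the long-gap rule.
* **Case mix.** Six age bands weighted toward 60–79 years, 71% male,
  log-normal stays (median about 40 h, a quarter shorter than a day — which
  is what makes the stay-too-short exclusion bite), 8.9% in-hospital
  mortality as an inert demographic flag, and heights emitted only as
  decade ranges to force the IBW midpoint path.
* **Event signature.** A configured fraction of patients (4.2% default)
  receive: a 12-h prodromal linear decline of diuresis; a sustained
  oliguric phase of 24–40 h at mean 0.20 ml/kg/h (clipped to at most
  0.30); and a creatinine rise to 2.5 times the pre-event level over 6 h
  from phase start. The truth table records the first hour at which the
  stage-2 urine run rule is satisfiable (12 h after the phase starts) as
  the onset, plus the phase start itself, and is segregated in
  `truth.csv` so the pipeline cannot consume it.
* **Non-events.** Healthy diuresis is log-normal (median 1.1 ml/kg/h,
  hour-to-hour log-sd 0.45, a patient-level random effect) so transient
  sub-0.5 dips occur without ever sustaining a 13-hour run; 8% of controls
  additionally get a 4–9 h mild oliguria episode (stage-1 territory), which
  keeps specificity honest; 2% of controls have no creatinine records.

The phase depth deserves a note: equal-split resampling of records with
fractional-hour timestamps can concentrate nearly two hours of volume into
one whole-hour bin, inflating single-bin rates by up to a factor of two.
The oliguric depth ceiling of 0.30 ml/kg/h guarantees that this charting
aliasing cannot lift a phase bin above the 0.5 ml/kg/h threshold and break
the KDIGO run — severe stage 2/3 episodes hovering near the stage-3
0.3 ml/kg/h band are also the clinically coherent picture.

The generator deliberately does **not** model comorbidities, medications,
diuretic boluses, renal-replacement sessions, mortality processes, device
artefacts, or unit errors, and its distributions are not fitted to any real
database. Consequently, a pipeline that passes all tests here is verified
in its *logic* — imputation arithmetic, staging, endpoint composition,
window geometry, leakage-free splitting, metric identities — and shown to
recover a realistic signal; the tests say nothing about the discrimination
the models would reach on real ICU data, where the signal is weaker and
confounded.

## Numerical and reproducibility choices

Boundary semantics are strict everywhere ("shorter than 9 h" excludes 9;
"less than 4 days" means at most 95 carried hours) and tested explicitly.
Thresholds sweep actual score values, so no interpolation is involved;
operating-point ties break toward the higher threshold (fixed sensitivity)
or higher sensitivity (knee). One global seed is fanned out to per-stage
seeds by a fixed derivation (`derive_seeds()`), so cohort generation,
splitting and network training are independently reproducible; identical
configurations produce byte-identical cohort files. Models serialise to a
versioned JSON of weights, architecture and standardisation constants.

The bundled checks run the full design at 2,000 + 2,000 patients — large
enough for roughly 60–90 event patients and 1,000+ positive windows per
cohort, which stabilises the external AUC to a few hundredths while keeping
a complete run around a minute on one CPU; the component checks use
1,000 random 200-hour staging sequences and a 50,000-row coefficient
recovery, sizes at which their brute-force oracles are still quick.

## Known limitations

The creatinine side of the endpoint (stage floor 1 within ±12 h) is the
permissive reading of "simultaneous"; a stricter reading (floor 2) labels
fewer, later episodes — both are one argument away. The knee-point
definition, patient-level aggregation, window stride and the deep model's
horizon are package choices where the source analyses are silent. The
Hanley–McNeil standard error treats windows as independent, which
window-level clustering within patients violates; patient-level AUCs and a
seeded bootstrap would be the conservative alternative. The conv net is a
faithful small instance of the architecture family, not a reconstruction
of any particular trained network, and no pre-trained weights are shipped.

## A minimal run

```{r eval = FALSE}
cfg <- pipeline_config(n_patients_a = 600, n_patients_b = 600, seed = 1)
res <- run_study(cfg, verbose = TRUE)
res$report
```
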