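---
title: "Mask-aware hierarchical attention networks for longitudinal EHR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mask-aware hierarchical attention networks for longitudinal EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hanEHR)
```

## The problem

Routinely collected primary-care records describe each patient as an
irregular stream of events — diagnoses, laboratory tests, clinical
measurements, consultations, admissions, dispensed drugs. In an ageing
cohort these streams are the raw material for predicting outcomes such as
all-cause mortality, nursing-home admission (ICD-10 `Z59.3`) and home-care
need (ICD-10 `Z74*`) over a 1- or 5-year horizon. Two features of such data
dominate the modelling problem:

* **Dynamic membership.** Patients enter the cohort when they become
  eligible (turning 65, or arriving in the catchment area) and leave at
  death, loss to follow-up or study end, so histories have very different
  lengths and calendar anchors.
* **Informative sparsity.** Within an observed year, most variables are
  simply never measured. An unrecorded value is not a measured zero, and a
  year of follow-up with no laboratory tests is not the same as a year
  outside the cohort.

hanEHR addresses both with *annual aggregation* plus *double masking*: each
patient becomes a `[T_max x 246]` matrix of yearly feature values, a
**period mask** `m_t` marking real follow-up years versus zero-padding, and
a **value mask** `m_{t,v}` marking recorded values within real years. The
mask hierarchy `m_{t,v} <= m_t` is asserted on every tensor the package
builds.

## The feature schema

The 246 dynamic variables fall into eight families: 60 chronic-disease
occurrence flags, 37 frailty deficits, 67 laboratory variables, 50 clinical
measurements, 8 consultation counts, 9 admission counts, 3 billed-drug
counts and 12 acute-event counts; sex and socioeconomic quintile are
static, for 248 variables in total. The clinical identity of each variable
is a structural stand-in (family prefix + index): the published variable
catalogue behind the original feature set is not redistributable, and every
computation in the package depends only on the counts, value types and
aggregation kinds, which are reproduced exactly. Two decompositions were
open and fixed as follows: the 67 laboratory variables are 22 analytes x
(test count, annual mean, out-of-reference-range count) + 1 total test
count, and the 50 measurements are 23 numeric x (count, mean) + 2
categorical x (count, mode).

Aggregation kinds and their missingness semantics:

| kind         | value                                  | recorded flag |
|--------------|----------------------------------------|---------------|
| `count`      | events in the year                     | always 1 in a real year (known zero) |
| `oor_count`  | lab tests outside the reference range  | always 1      |
| `mean`       | mean of the year's measurements        | 1 only if measured |
| `mode`       | most frequent category (ties: smallest)| 1 only if measured |
| `flag_carry` | once-present-always-present occurrence | always 1      |

Chronic-disease and frailty flags carry forward because chronicity implies
persistence; acute counts do not. Aggregation uses calendar years, and each
patient's prediction index is their last follow-up year minus the window,
which maximizes usable history with a single index per patient.
Right-alignment (padding on the *left*) makes "the year closest to the
prediction" a fixed column across patients, which is what lets population
attention maps be averaged slot-wise.

## The model

For one patient, with `x_{t,v}` the normalized value and the two masks as
above:

1. **Per-variable lifting.** Each scalar is lifted to `e_{t,v} = x_{t,v}
   E_v + b_v` with a learned per-variable embedding (`E_v, b_v` of
   dimension 8 by default); a recurrent layer needs a vector per step and
   the embedding also gives each variable an identity. Rows of `E` are
   initialized at the per-row Glorot scale (fan-in 1).
2. **Variable-level recurrence + attention.** A recurrent layer (GRU or
   LSTM, `U` units) consumes the `V = 246` lifted values of period `t` in
   fixed schema order. Steps with `m_{t,v} = 0` are *skipped*: the hidden
   state passes through unchanged. Each step's output `h_{t,v}` is scored
   by additive (Bahdanau-style) attention `s_{t,v} = w^T tanh(W h_{t,v} +
   b)` and the scores are **mask-softmaxed** over `m_{t,v}`: masked
   variables get weight exactly 0, the rest sum to 1, giving
   `alpha_{t,v}` and the period context `c_t = sum_v alpha_{t,v} h_{t,v}`.
3. **Time-level recurrence + attention.** A bidirectional recurrent layer
   (same type and units) runs over the period contexts, again with
   state-pass-through at padded periods; the concatenated direction outputs
   are scored and mask-softmaxed over `m_t`, giving `beta_t` and the
   patient summary `z = sum_t beta_t g_t`.
4. **Static fusion and head.** `z` is concatenated with the static
   features (sex, centred socioeconomic quintile), optionally passed
   through one ReLU dense layer of `U` units, and mapped to an outcome
   probability by a sigmoid unit.

The `alpha` and `beta` weights are the transparency layer: nonnegative,
exactly zero on masked slots, normalized within every real period and over
every patient's real periods.

Because masked steps pass state through unchanged and the attention is
mask-restricted, two contracts hold *exactly* (not just approximately) and
are asserted over seeded random patients in the test suite:

* **Padding invariance** — prepending all-padded periods leaves the output
  probability unchanged;
* **Missing invariance** — perturbing values at masked positions changes
  nothing (inputs are re-zeroed by the mask inside the forward pass).

The exact score function, scalar embedding and bidirectional merge are
design choices of this package: additive attention on recurrent outputs,
learned linear lifting, and concatenation of the two directions. Time
attention is computed from the bidirectional outputs only, not conditioned
on statics.

## Training protocol

Patient-level splits: 10% test, then 15% of the remainder for validation.
Normalization (z-scoring of numeric variables by training-set masked means
and population SDs; zero-variance variables map to 0; binary/categorical
variables pass through) is fitted strictly on the training patients and
stored inside the fitted model, so prediction on raw tensors can never
leak. Grid search covers {GRU, LSTM} x {64, 128, 256, 512} units x {0, 1}
dense layers — 16 configurations — targeting validation ROC-AUC, with ties
broken by fewer parameters then grid order, and a half epoch budget
relative to the final fit. The winner is retrained from a fresh seeded
initialization on train + validation; the test set is untouched until
evaluation.

The optimizer is Adam on binary cross-entropy. The package defaults —
**batch 64, learning rate 1e-2, 8 epochs, early-stopping patience 5 on
validation ROC-AUC** — were chosen because the attention softmax over 246
variables starts nearly uniform and needs on the order of a hundred
optimizer steps before it concentrates on informative variables; larger
batches with smaller rates spend the same computation on far fewer steps
and can sit at the base-rate plateau for many epochs. All randomness
(initialization, shuffling, resampling) flows from explicit seeds, and a
single pipeline seed fans out to fixed per-stage seeds, so every stage is
independently replayable.

The network itself — GRU/LSTM cells, both attention levels, the masked
softmax and the full backward pass — is implemented in RcppArmadillo
inside the package. Gradient correctness is established by exhaustive
finite-difference checks at small dimensions in the test suite (worst
absolute deviation around `1e-11` at tolerance `1e-4` per parameter).

## Evaluation

Test-set metrics are Cohen's kappa, ROC-AUC (the rank/Mann–Whitney
statistic, equal to trapezoidal integration over all thresholds; the suite
verifies equality with brute-force pairwise concordance), PR-AUC (average
precision with tied scores grouped), precision and recall. Class metrics
use a 0.5 threshold by default — the neutral choice, recorded in every
report and overridable. Confidence intervals are 95% percentile bootstrap
with 1000 seeded resamples; resamples that draw a single class are redrawn
and counted. Calibration uses 20 right-closed bins of width 0.05 with
per-bin class counts, the construction behind a calibration plot with
per-class probability bars. Stratified reports (sex, age at entry with
default edges 65–74 / 75–84 / 85+) reuse the same machinery.

Cross-sectional baselines — logistic regression, random forest (`ranger`),
gradient-boosted trees (`xgboost`), all with their engines' documented
defaults, seeded and recorded — see each patient's *first observed year*
only, with missing cells imputed by training-set means/modes of patients of
the same integer age and sex (falling back to age ±2, then sex only, then
the global statistic). They share the longitudinal model's split exactly.

## The synthetic cohort generator

The original study population is confidential, so the generator is the
package's study bed, and its defaults *are* the study conditions: a
2010–2019 window, entry at 65+ with 10% of prevalent-age patients
in-migrating uniformly over the window, exponential loss to follow-up at
2%/year, per-patient yearly visit intensity uniform on [0.5, 8], and
laboratory tests and measurements only in years with at least one visit —
which is precisely the missingness the value mask must absorb. Outcome
prevalences default to 24% / 9% / 14% (mortality / nursing home / home
care), in the vicinity of the 1-year task rates reported for the original
cohort.

Outcomes are drawn from a known logistic model: a planted risk
specification lists variables, effect sizes on the population-standardized
scale, and recency profiles (`last_year_only`, `uniform`, or `decaying`
with ratio 0.5 per year), applied to the patient's aggregated history at
the index year. The default plants strong effects (2.0) on two acute-event
counts and one admission count through the last history year only. Acute
counts are independent across years, so this signal is (i) invisible to
first-year baselines, (ii) recoverable by the attention maps, and (iii)
concentrated on the most recent period, making the qualitative claims —
longitudinal beats cross-sectional, top-attention variables are the planted
ones, time attention peaks at the final period — all testable. Event dates
inside the outcome window are uniform; for the 1-year task this is exactly
consistent with the tensorizer's per-patient index rule, while for the
5-year task a mid-window death shifts the realized index earlier than the
planted one, diluting (not biasing) recovery — the recovery experiments
therefore use the 1-year task.

What the generator does *not* emulate: real code frequencies and
comorbidity correlations, within-year visit clustering, free text,
calendar trends, or the true prevalence table of any real population.
Passing the recovery tests shows the architecture extracts planted
longitudinal signal under realistic missingness — not that it matches the
published performance on confidential data, which is out of reach by
construction.

## Numerical choices and degenerate inputs

* Masked softmax subtracts the unmasked maximum before exponentiation; an
  all-masked input returns an all-zero vector with a flag, and the
  consumer skips the slot. A real year in which nothing was recorded
  yields a zero context and zero attention row (with a warning at the
  encoding surface).
* Zero-variance variables normalize to 0; missing socioeconomic quintile
  enters the network as the centred value 0.
* Mode ties break toward the smallest category; attention ranking ties
  break in schema order and are flagged.
* LSTM forget-gate biases initialize at 1; all other biases at 0.
* Population attention maps average only over patients contributing a real
  period at each slot; patient maps min–max rescale only the displayed
  top-k values (display-only — raw weights are always reported alongside,
  since variable-level weights are necessarily much smaller than
  time-level ones).
* Variable order inside the per-period recurrence is the fixed schema
  order; it is registered in the tensor so permutation sensitivity can be
  studied.

## Problem sizes

The test suite trains one GRU model with 64 units on a 5000-patient
synthetic cohort (about 4700 eligible) for its recovery and
baseline-comparison checks, and a handful of much smaller models; the
acceptance script uses 2000 patients with 32 units. These sizes were chosen
so that the planted-signal experiments sit well above their decision
margins (test ROC-AUC ≈ 0.90–0.945 against a 0.85 bound; recovery 3/3
planted variables in the top decile) while a complete run stays in the
minutes range on a single CPU. Larger cohorts sharpen the same
conclusions.

## Known limitations

* Single prediction index per patient; per-year multi-indexing is out of
  scope.
* Three outcomes are three separately trained models; no multi-task head.
* Attention maps are reported as transparency, not causal attribution —
  attention weights need not coincide with feature importance in the
  perturbation sense.
* The grid search trains each configuration once (no nested
  cross-validation), faithfully to the original protocol.
* The synthetic schema is structural: variable names carry no clinical
  meaning.
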