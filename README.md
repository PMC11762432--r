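# hanEHR

Hierarchical attention recurrent networks for predicting health outcomes —
all-cause mortality, nursing-home admission (ICD-10 `Z59.3`) and home-care
need (`Z74*`) — in ageing populations from irregularly sampled,
annually aggregated primary-care records.

Routine EHR data arrive as variable-length, sparsely observed patient
histories: people enter a cohort when they turn 65 or move in, leave at
death or loss to follow-up, and most clinical variables are simply never
measured in a given year. hanEHR handles this with **double masking** — a
period mask `m_t` marking real follow-up years versus zero-padding, and a
value mask `m_{t,v}` marking recorded values within real years — threaded
through every layer of a two-level attention recurrent network:

1. a recurrent layer (GRU or LSTM, `U` units) reads the 246 annual
   variables of each year as a sequence; additive attention restricted to
   the value mask produces variable weights `α_{t,v}` (zero on unrecorded
   values, summing to 1 per real year) and a year context
   `c_t = Σ_v α_{t,v} h_{t,v}`;
2. a bidirectional recurrent layer reads the year contexts; masked
   attention over real years produces time weights `β_t` and the patient
   summary `z = Σ_t β_t g_t`, which is fused with static features (sex,
   socioeconomic quintile) and mapped to an outcome probability.

Masked recurrent steps pass their state through unchanged, so padding
invariance and missing-value invariance hold *exactly*. The `α`/`β`
weights double as the model's transparency layer: population- and
patient-level attention maps show which variables in which years drove a
prediction.

The package implements the complete study protocol around the network:

* a **246 + 2 variable schema** (chronic-disease flags, frailty deficits,
  laboratory counts/means/out-of-range counts, clinical measurements,
  consultations, admissions, billed drugs, acute events, plus sex and
  socioeconomic quintile) with per-family annual aggregation rules;
* a **cohort tensorizer**: record cleaning (duplicate/implausible/
  wrong-sex diagnoses), dynamic-cohort eligibility (65+, under 100 at
  study start, minimum follow-up of window + 1 years), label derivation
  over 1- or 5-year windows, zero-padded doubly-masked tensors,
  training-split-only normalization;
* the **training protocol**: patient-level 90/10 then 85/15 splits, grid
  search over {GRU, LSTM} × {64, 128, 256, 512} units × {0, 1} dense
  layers targeting validation ROC-AUC, merged retrain, Adam with early
  stopping — the network itself (forward and analytic backward pass) is
  implemented in RcppArmadillo inside the package;
* **evaluation**: Cohen's kappa, ROC-AUC, PR-AUC, precision, recall with
  95% percentile bootstrap intervals (1000 seeded resamples), 20-bin
  calibration tables and plots, sex/age-stratified reports;
* **cross-sectional baselines** (logistic regression, ranger random
  forest, xgboost) on first-observed-year features with age/sex mean-mode
  imputation, sharing the identical split;
* a seeded **synthetic cohort generator** with planted, recoverable
  logistic risk (configurable effect sizes and recency profiles), standing
  in for the confidential primary-care database the design targets.

## Worked example

Simulate a 2000-patient dynamic cohort (2010–2019), build the 1-year-window
tensor, train, evaluate, and inspect the attention maps:

```r
library(hanEHR)

schema <- build_default_schema()
cohort <- generate_cohort(synthetic_config(n_patients = 2000, seed = 1),
                          schema)
tz <- tensorize(cohort$events, cohort$statics, schema,
                eligibility_config(window = 1))
tz$tensor
#> <feature_tensor> 1897 patients x 9 periods x 246 variables (+2 static)
#>   real periods: 7.2 mean, 9 max

plan <- make_splits(tz$tensor$patient_ids, seed = 2)
#> <split_plan> train 1452 / val 256 / test 189 (seed 2)

model <- han_fit(tz$tensor, tz$labels, "mortality",
                 model_config("GRU", units = 32, seed = 3), schema,
                 train_ids = plan$train, val_ids = plan$val)

att <- predict(model, tz$tensor, attention = TRUE)
te <- match(plan$test, tz$tensor$patient_ids)
metrics_report(tz$labels$mortality[te], att$p[te], seed = 4)
#>          metric     point    ci_low   ci_high
#> 1: cohens_kappa 0.5442553 0.4074087 0.6814301
#> 2:      roc_auc 0.8930233 0.8447829 0.9324674
#> 3:       pr_auc 0.7907699 0.6740674 0.8806955
#> 4:    precision 0.8250000 0.6969066 0.9348001
#> 5:       recall 0.5500000 0.4210336 0.6727273
```

The point estimates come with percentile bootstrap intervals on the
189-patient test set; class metrics use the default 0.5 threshold. The
generator planted its risk on `event_01`, `event_02` and `adm_01` through
the *last history year only* — and the test-set attention maps recover
exactly that:

```r
pm <- population_map(list(alpha = att$alpha[te, , , drop = FALSE],
                          beta = att$beta[te, , drop = FALSE]),
                     subset_tensor(tz$tensor, plan$test))
head(pm$variable_ranking, 5)
#>    variable_id mean_alpha  rank
#> 1:    event_02 0.11638506     1
#> 2:    event_03 0.10427803     2
#> 3:    event_01 0.09924090     3
#> 4:      adm_01 0.07107632     4
#> 5:    event_04 0.04626986     5

round(pm$mean_beta, 4)
#> [1] 0.0003 0.0003 0.0003 0.0004 0.0004 0.0005 0.0006 0.0040 0.9941

planted_signal_report(cohort$truth, pm)$recovery_fraction
#> [1] 1
```

All three planted variables sit in the top four by mean variable attention
(recovery fraction 1 within the top decile), and the time attention puts
99.4% of its weight on the year closest to the prediction, matching the
planted last-year-only recency. `render_maps(pm, "map.png")` draws the
population heatmap (top-10 variables plus the time-attention column) and
writes the plotted values as CSV; `patient_map()` gives the per-patient
top-5-per-year view.

`run_pipeline()` composes all of the above (simulate → tensorize → train →
evaluate → baselines → explain) into one seeded, manifest-writing run, and
a thin command-line interface over the same functions ships at
`system.file("cli/hanehr.R", package = "hanEHR")` with subcommands
`simulate`, `tensorize`, `train`, `evaluate`, `baselines`, `explain` and
`demo`.

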