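test_that("identical seeds give byte-identical cohorts", {
  cfg <- synthetic_config(n_patients = 120L, seed = 7L)
  a <- generate_cohort(cfg, fixture_schema())
  b <- generate_cohort(cfg, fixture_schema())
  expect_identical(a$events, b$events)
  expect_identical(a$statics, b$statics)
  expect_identical(a$truth$outcomes, b$truth$outcomes)
})

test_that("different seeds give different cohorts", {
  a <- generate_cohort(synthetic_config(n_patients = 120L, seed = 7L))
  b <- generate_cohort(synthetic_config(n_patients = 120L, seed = 8L))
  expect_false(identical(a$events, b$events))
})

test_that("no events precede cohort entry (dynamic entry rule)", {
  cd <- fixture_cohort()
  ev <- cd$events
  st <- cd$statics
  entry <- st$registry_entry_date[match(ev$patient_id, st$patient_id)]
  # entry is max(study start, 65th birthday, arrival); events are recorded
  # from the entry year onward
  expect_true(all(as.integer(format(ev$date, "%Y")) >=
                    as.integer(format(entry, "%Y"))))
  b65 <- st$birth_date[match(ev$patient_id, st$patient_id)] +
    round(65 * 365.25)
  expect_true(all(ev$date >= pmin(b65, as.Date("2010-01-01")) |
                    ev$date >= b65))
})

test_that("zero visit intensity removes every lab and measurement", {
  cfg <- synthetic_config(n_patients = 80L, seed = 3L,
                          visit_rate_range = c(0, 0))
  cd <- generate_cohort(cfg, fixture_schema())
  expect_identical(nrow(cd$events[cd$events$domain %in%
                                    c("lab", "measure"), ]), 0L)
  expect_identical(nrow(cd$events[cd$events$domain == "visit", ]), 0L)
})

test_that("zero effects reproduce the configured base rate", {
  rs <- default_risk_spec()
  rs$effect_size <- 0
  cfg <- synthetic_config(n_patients = 10000L, seed = 5L, risk_spec = rs,
                          outcome_base_rates = c(mortality = 0.2,
                                                 nursing_home = 0.09,
                                                 home_care = 0.14))
  cd <- generate_cohort(cfg, fixture_schema())
  draws <- cd$truth$outcomes[, "mortality"]
  n <- sum(!is.na(draws))
  rate <- mean(draws, na.rm = TRUE)
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(rate - 0.2), 3 * se)
})

test_that("configuration is validated", {
  expect_error(synthetic_config(n_patients = 0), "positive")
  expect_error(synthetic_config(study_start = "2020-01-01",
                                study_end = "2010-01-01"), "precede")
  rs <- default_risk_spec(); rs$effect_size[1] <- Inf
  expect_error(synthetic_config(risk_spec = rs), "finite")
  expect_error(synthetic_config(outcome_base_rates = c(
    mortality = 0, nursing_home = 0.1, home_care = 0.1)))
  rs2 <- default_risk_spec(); rs2$variable_id[1] <- "nonexistent"
  expect_error(generate_cohort(synthetic_config(n_patients = 20L,
                                                risk_spec = rs2)),
               "not in schema")
})

test_that("cohort tables round-trip through CSV and Parquet", {
  cd <- fixture_cohort()
  d1 <- file.path(tempdir(), "coh_csv")
  write_cohort(cd$events, cd$statics, d1, format = "csv")
  back <- read_cohort(d1, format = "csv")
  expect_identical(back$events$date, cd$events$date)
  expect_identical(back$events$code, cd$events$code)
  expect_identical(back$statics$death_date, cd$statics$death_date)
  unlink(d1, recursive = TRUE)
  skip_if_not_installed("arrow")
  d2 <- file.path(tempdir(), "coh_parquet")
  write_cohort(cd$events, cd$statics, d2, format = "parquet")
  back2 <- read_cohort(d2, format = "parquet")
  expect_equal(back2$events$value, cd$events$value)
  expect_identical(as.Date(back2$statics$birth_date), cd$statics$birth_date)
  unlink(d2, recursive = TRUE)
})

test_that("stronger planted effects separate outcome probabilities", {
  cd <- fixture_cohort()
  pr <- cd$truth$outcome_probs[, "mortality"]
  expect_gt(sd(pr, na.rm = TRUE), 0.1)  # real signal, not a constant rate
  lin <- cd$truth$linear_predictor
  expect_true(all(is.finite(lin)))
})
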