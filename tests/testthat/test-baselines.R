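test_that("cross-section extracts each patient's first real period", {
  cd <- fixture_cohort()
  xs <- build_cross_section(cd$tz$tensor, cd$statics)
  t <- cd$tz$tensor
  expect_identical(nrow(xs), length(t$patient_ids))
  i <- 1L
  first_slot <- which(t$period_mask[i, ] == 1)[1]
  expect_identical(xs$first_year[i], t$period_years[i, first_slot])
  # masked cells are NA, recorded cells carry the raw value
  v_missing <- which(t$value_mask[i, first_slot, ] == 0)[1]
  v_present <- which(t$value_mask[i, first_slot, ] == 1)[1]
  expect_true(is.na(xs[[t$variable_index[v_missing]]][i]))
  expect_identical(xs[[t$variable_index[v_present]]][i],
                   t$X[i, first_slot, v_present])
})

test_that("age/sex imputation reproduces the brute-force group mean", {
  cd <- fixture_cohort()
  xs <- build_cross_section(cd$tz$tensor, cd$statics)
  train <- xs$patient_id[1:200]
  imp <- impute_age_sex(xs, train)
  expect_false(anyNA(imp[, setdiff(names(imp),
                                   c("patient_id", "age", "sex",
                                     "first_year")), with = FALSE]))
  # pick a missing numeric cell whose (age, sex) training cell is non-empty
  col <- "lab_01_mean"
  miss <- which(is.na(xs[[col]]))
  tr <- xs[xs$patient_id %in% train, ]
  found <- FALSE
  for (i in miss) {
    cell <- tr[[col]][tr$age == xs$age[i] & tr$sex == xs$sex[i]]
    if (sum(!is.na(cell)) > 0) {
      expect_equal(imp[[col]][i], mean(cell, na.rm = TRUE))
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("imputation is an identity on complete columns", {
  cd <- fixture_cohort()
  xs <- build_cross_section(cd$tz$tensor, cd$statics)
  imp <- impute_age_sex(xs, xs$patient_id)
  complete <- names(which(!vapply(xs, anyNA, logical(1))))
  for (cc in intersect(complete, c("visit_01", "chronic_01", "adm_01")))
    expect_identical(imp[[cc]], xs[[cc]])
})

test_that("imputation falls back sex-only then global for empty cells", {
  tab <- data.table::data.table(
    patient_id = c("a", "b", "c", "d"),
    age = c(70L, 70L, 91L, 95L),
    sex = c("F", "F", "M", "M"),
    ses_quintile = c(1L, 1L, 2L, 2L),
    first_year = 2010L,
    glucose = c(100, NA, 80, NA)
  )
  # b: same (age, sex) cell has a -> 100; d: no 95 +/- 2 cell, falls back
  # to sex M mean (80)
  imp <- impute_age_sex(tab, train_ids = c("a", "c"),
                        categorical = "ses_quintile")
  expect_equal(imp$glucose[2], 100)
  expect_equal(imp$glucose[4], 80)
  # global fallback when the whole sex stratum is empty in training
  imp2 <- impute_age_sex(tab, train_ids = "a",
                         categorical = "ses_quintile")
  expect_equal(imp2$glucose[4], 100)
})

test_that("all three comparators share the report schema and are seeded", {
  cd <- fixture_cohort()
  xs <- build_cross_section(cd$tz$tensor, cd$statics)
  plan <- make_splits(cd$tz$tensor$patient_ids, seed = 8L)
  imp <- impute_age_sex(xs, c(plan$train, plan$val))
  fits <- lapply(c("logistic", "random_forest", "boosted_trees"),
                 function(mm) fit_baselines(imp, cd$tz$labels, "mortality",
                                            plan, mm, seed = 11L, B = 50L))
  for (f in fits) {
    expect_s3_class(f$report, "metrics_report")
    expect_identical(f$report$metric,
                     c("cohens_kappa", "roc_auc", "pr_auc", "precision",
                       "recall"))
    expect_identical(names(f$p_test), plan$test[match(names(f$p_test),
                                                      plan$test)])
  }
  refit <- fit_baselines(imp, cd$tz$labels, "mortality", plan,
                         "random_forest", seed = 11L, B = 50L)
  expect_identical(fits[[2]]$report$point, refit$report$point)
})

test_that("logistic regression nails a single strong linear feature", {
  set.seed(13)
  n <- 1200
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(4 * x))
  tab <- data.table::data.table(
    patient_id = sprintf("P%04d", 1:n), age = 70L, sex = "F",
    ses_quintile = 3L, first_year = 2010L, feat = x)
  labels <- data.frame(patient_id = tab$patient_id, y = y)
  plan <- make_splits(tab$patient_id, seed = 2L)
  fit <- fit_baselines(tab, labels, "y", plan, "logistic", B = 50L)
  auc <- fit$report$point[fit$report$metric == "roc_auc"]
  expect_gte(auc, 0.95)
})
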