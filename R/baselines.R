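#' Cross-sectional table from the first observed year
#'
#' Extracts, for every patient, the feature vector of their first real
#' (unmasked) period, together with static features and the age at that
#' first year. Cells with `value_mask = 0` are marked missing (`NA`) for
#' subsequent imputation. This is the input representation of the
#' cross-sectional baseline models, which see only one year of data.
#'
#' @param tensor A raw `feature_tensor`.
#' @param statics Static patient table.
#' @return A `data.table` with `patient_id`, `age`, `sex`, `ses_quintile`,
#'   `first_year` and one column per dynamic variable (NA = unrecorded).
#' @export
build_cross_section <- function(tensor, statics) {
  statics <- data.table::as.data.table(statics)
  n <- dim(tensor$X)[1]
  first_slot <- apply(tensor$period_mask, 1, function(r) which(r == 1)[1])
  if (anyNA(first_slot)) stop("patient with zero real periods")
  X1 <- matrix(NA_real_, n, dim(tensor$X)[3],
               dimnames = list(NULL, tensor$variable_index))
  for (i in seq_len(n)) {
    x <- tensor$X[i, first_slot[i], ]
    x[tensor$value_mask[i, first_slot[i], ] == 0] <- NA_real_
    X1[i, ] <- x
  }
  idx <- match(tensor$patient_ids, statics$patient_id)
  first_year <- tensor$period_years[cbind(seq_len(n), first_slot)]
  age <- first_year - year_of(statics$birth_date[idx])
  out <- data.table::data.table(
    patient_id = tensor$patient_ids,
    age = as.integer(age),
    sex = statics$sex[idx],
    ses_quintile = statics$ses_quintile[idx],
    first_year = first_year
  )
  cbind(out, data.table::as.data.table(X1))
}

#' Age/sex mean-mode imputation
#'
#' Fills missing cells with the mean (numeric) or mode (categorical) of
#' training-split patients of the same integer age and sex. Sparse cells
#' fall back to age +/- 2 years within the same sex, then to the sex-only
#' statistic, then to the global training statistic. Imputation values are
#' learned from training rows only.
#'
#' @param table A [build_cross_section()] table.
#' @param train_ids Training patient ids (imputation source).
#' @param categorical Variable names treated as categorical (mode
#'   imputation); defaults to mode-aggregated variables and
#'   `ses_quintile`.
#' @return The imputed table (no missing cells) with an
#'   `imputation_counts` attribute.
#' @export
impute_age_sex <- function(table, train_ids,
                           categorical = NULL) {
  dt <- data.table::copy(data.table::as.data.table(table))
  if (is.null(categorical))
    categorical <- c(grep("_mode$", names(dt), value = TRUE), "ses_quintile")
  feat_cols <- setdiff(names(dt), c("patient_id", "age", "sex",
                                    "first_year"))
  tr <- dt[dt$patient_id %in% train_ids, ]
  counts <- integer(0)

  mode_of <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    tab <- sort(table(x), decreasing = TRUE)
    as.numeric(names(tab)[1])
  }

  for (cc in feat_cols) {
    miss <- which(is.na(dt[[cc]]))
    if (!length(miss)) next
    counts[cc] <- length(miss)
    is_cat <- cc %in% categorical
    stat <- if (is_cat) mode_of else function(x) mean(x, na.rm = TRUE)
    glob <- stat(tr[[cc]])
    by_sex <- tr[, .(v = stat(.SD[[1]])), by = sex, .SDcols = cc]
    filled <- numeric(length(miss))
    for (k in seq_along(miss)) {
      i <- miss[k]
      a <- dt$age[i]; s <- dt$sex[i]
      cand <- tr[[cc]][tr$sex == s & tr$age == a]
      v <- stat(cand)
      if (is.na(v)) {
        cand <- tr[[cc]][tr$sex == s & abs(tr$age - a) <= 2]
        v <- stat(cand)
      }
      if (is.na(v)) v <- by_sex$v[match(s, by_sex$sex)]
      if (is.na(v)) v <- glob
      filled[k] <- v
    }
    data.table::set(dt, miss, cc, filled)
  }
  if (anyNA(dt[, ..feat_cols]))
    stop("imputation left missing cells (variable entirely missing in training data)")
  data.table::setattr(dt, "imputation_counts", counts)
  dt
}

#' Fit a cross-sectional baseline comparator
#'
#' Trains logistic regression, random forest or gradient-boosted trees on
#' the imputed first-year table with library-default hyperparameters
#' (seeded), using the same patient split plan as the longitudinal model,
#' and evaluates on the test split with the shared bootstrap protocol.
#'
#' @param table An imputed [impute_age_sex()] table.
#' @param labels Label table with the outcome column.
#' @param outcome Outcome name.
#' @param plan The shared [make_splits()] plan.
#' @param model `"logistic"`, `"random_forest"` or `"boosted_trees"`.
#' @param seed Seed for the stochastic learners.
#' @param threshold Classification threshold for class metrics.
#' @param B Bootstrap resamples for the report.
#' @return A list of class `baseline_fit`: `model`, `model_name`,
#'   `p_test` (named), `report` (a `metrics_report`), `hyperparameters`.
#' @export
fit_baselines <- function(table, labels, outcome, plan,
                          model = c("logistic", "random_forest",
                                    "boosted_trees"),
                          seed = 1L, threshold = 0.5, B = 1000L) {
  model <- match.arg(model)
  dt <- data.table::as.data.table(table)
  labels <- data.table::as.data.table(labels)
  y <- labels[[outcome]][match(dt$patient_id, labels$patient_id)]
  if (anyNA(y)) stop("labels missing for some patients in the table")

  feat_cols <- setdiff(names(dt), c("patient_id", "first_year"))
  Xm <- as.matrix(data.table::as.data.table(
    lapply(dt[, ..feat_cols], function(x)
      if (is.character(x)) as.numeric(factor(x, levels = sort(unique(x))))
      else as.numeric(x))))

  tr_rows <- which(dt$patient_id %in% c(plan$train, plan$val))
  te_rows <- which(dt$patient_id %in% plan$test)
  if (length(unique(y[tr_rows])) < 2)
    stop("single-class training labels: baseline undefined")

  set.seed(seed)
  hyper <- list()
  if (model == "logistic") {
    df <- data.frame(y = y[tr_rows], Xm[tr_rows, , drop = FALSE])
    # wide cross-sectional tables are routinely collinear at moderate n;
    # rank-deficiency warnings are expected and the fit is well defined
    fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    p_test <- as.numeric(suppressWarnings(predict(
      fit, newdata = data.frame(Xm[te_rows, , drop = FALSE]),
      type = "response")))
    hyper <- list(engine = "stats::glm", family = "binomial")
  } else if (model == "random_forest") {
    df <- data.frame(y = factor(y[tr_rows]), Xm[tr_rows, , drop = FALSE])
    fit <- ranger::ranger(y ~ ., data = df, probability = TRUE,
                          seed = seed)
    pr <- predict(fit, data = data.frame(Xm[te_rows, , drop = FALSE]))
    p_test <- pr$predictions[, "1"]
    hyper <- list(engine = "ranger", num.trees = fit$num.trees,
                  mtry = fit$mtry)
  } else {
    dtr <- xgboost::xgb.DMatrix(Xm[tr_rows, , drop = FALSE],
                                label = y[tr_rows])
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = 0.3,
                    max_depth = 6, nthread = 1, seed = seed),
      data = dtr, nrounds = 100, verbose = 0)
    p_test <- predict(fit, xgboost::xgb.DMatrix(
      Xm[te_rows, , drop = FALSE]))
    hyper <- list(engine = "xgboost", nrounds = 100, eta = 0.3,
                  max_depth = 6)
  }
  report <- metrics_report(y[te_rows], p_test, threshold = threshold,
                           B = B, seed = seed)
  structure(list(model = fit, model_name = model,
                 p_test = setNames(p_test, dt$patient_id[te_rows]),
                 report = report, hyperparameters = hyper),
            class = "baseline_fit")
}
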