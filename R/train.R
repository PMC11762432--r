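#' Patient-level holdout split plan
#'
#' Seeded shuffle into test (10%), then validation (15% of the remainder)
#' and training sets, always by patient id, never by row. With 1000 ids the
#' memberships are 100 test / 135 validation / 765 training.
#'
#' @param patient_ids Character vector of ids.
#' @param seed Split seed.
#' @param test_fraction Fraction held out for testing (default 0.10).
#' @param val_fraction_of_train Fraction of the remainder used for
#'   validation during tuning (default 0.15).
#' @return A list of class `split_plan` with `train`, `val`, `test`.
#' @export
make_splits <- function(patient_ids, seed,
                        test_fraction = 0.10,
                        val_fraction_of_train = 0.15) {
  if (length(patient_ids) < 10) stop("need at least 10 patients to split")
  if (anyDuplicated(patient_ids)) stop("patient_ids must be unique")
  set.seed(seed)
  ids <- sample(patient_ids)
  n_test <- floor(length(ids) * test_fraction)
  test <- ids[seq_len(n_test)]
  rest <- ids[-seq_len(n_test)]
  n_val <- floor(length(rest) * val_fraction_of_train)
  val <- rest[seq_len(n_val)]
  train <- rest[-seq_len(n_val)]
  structure(list(train = train, val = val, test = test, seed = seed,
                 test_fraction = test_fraction,
                 val_fraction_of_train = val_fraction_of_train),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> train %d / val %d / test %d (seed %d)\n",
              length(x$train), length(x$val), length(x$test), x$seed))
  invisible(x)
}

#' The default hyperparameter grid
#'
#' Cartesian product of recurrent type (GRU, LSTM), units (64, 128, 256,
#' 512) and dense layer before output (0, 1): 16 configurations.
#'
#' @return A `data.frame` with columns `rnn_type`, `units`, `dense`.
#' @export
default_grid <- function() {
  g <- expand.grid(rnn_type = c("GRU", "LSTM"),
                   units = c(64L, 128L, 256L, 512L),
                   dense = c(0L, 1L),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[order(match(g$rnn_type, c("GRU", "LSTM")), g$units, g$dense), ,
    drop = FALSE][, c("rnn_type", "units", "dense")] -> g
  rownames(g) <- NULL
  g
}

#' Grid search over model configurations
#'
#' Trains one model per grid row on the training split, evaluates ROC-AUC
#' on the validation split, and returns the best configuration. Ties are
#' broken by fewer parameters, then grid order. A configuration that fails
#' to train is recorded as failed and excluded from the argmax; the search
#' continues. The grid epoch budget is half the final-fit budget.
#'
#' @param tensor Raw `feature_tensor`.
#' @param labels Label table.
#' @param outcome Outcome column name.
#' @param plan A [make_splits()] plan (fixed before any training).
#' @param schema Feature schema.
#' @param grid Data frame of configurations (default [default_grid()]).
#' @param epochs Final-fit epoch budget; the grid uses `ceiling(epochs/2)`.
#' @param seed Training seed (shared across configurations).
#' @param ... Passed to [han_fit()] (`batch_size`, `lr`, `patience`, ...).
#' @return A list of class `grid_result`: `results` (per-config validation
#'   ROC-AUC, parameter count, status), `best_config`, `best_val_auc`.
#' @export
grid_search <- function(tensor, labels, outcome, plan, schema,
                        grid = default_grid(), epochs = 10L, seed = 1L,
                        ...) {
  stopifnot(inherits(plan, "split_plan"))
  V <- dim(tensor$X)[3]; Vs <- ncol(tensor$S)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      cfg <- model_config(grid$rnn_type[i], grid$units[i], grid$dense[i],
                          seed = seed)
      np <- count_params(cfg, V, Vs)
      fit <- han_fit(tensor, labels, outcome, cfg, schema,
                     train_ids = plan$train, val_ids = plan$val,
                     epochs = ceiling(epochs / 2), ...)
      pv <- predict(fit, tensor)[match(plan$val, tensor$patient_ids)]
      y <- labels[[outcome]][match(plan$val, labels$patient_id)]
      list(val_auc = roc_auc(y, pv), n_params = np, status = "ok")
    }, error = function(e) list(val_auc = NA_real_, n_params = NA_integer_,
                                status = paste("failed:", conditionMessage(e))))
    rows[[i]] <- data.table::data.table(
      config_id = i, rnn_type = grid$rnn_type[i], units = grid$units[i],
      dense = grid$dense[i], n_params = res$n_params,
      val_auc = res$val_auc, status = res$status)
  }
  results <- data.table::rbindlist(rows)
  ok <- results[!is.na(results$val_auc), ]
  if (nrow(ok) == 0) stop("every grid configuration failed to train")
  ord <- order(-ok$val_auc, ok$n_params, ok$config_id)
  best <- ok[ord[1], ]
  structure(list(
    results = results,
    best_config = model_config(best$rnn_type, best$units, best$dense,
                               seed = seed),
    best_val_auc = best$val_auc
  ), class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("<grid_result>\n"); print(x$results)
  cat(sprintf("best: %s(%d), dense=%d, val AUC %.4f\n",
              x$best_config$rnn_type, x$best_config$units,
              x$best_config$dense, x$best_val_auc))
  invisible(x)
}

#' Final fit on merged training and validation sets
#'
#' Retrains the selected configuration from a fresh seeded initialization
#' on the union of the training and validation patients; the test set
#' remains untouched until evaluation.
#'
#' @inheritParams grid_search
#' @param config The winning [model_config()].
#' @param epochs Final epoch budget.
#' @param ... Passed to [han_fit()].
#' @return A fitted `han_model`.
#' @export
final_fit <- function(tensor, labels, outcome, plan, config, schema,
                      epochs = 10L, ...) {
  stopifnot(inherits(plan, "split_plan"))
  merged <- c(plan$train, plan$val)
  if (length(intersect(merged, plan$test)))
    stop("split plan leaks test patients into training")
  han_fit(tensor, labels, outcome, config, schema,
          train_ids = merged, val_ids = NULL, epochs = epochs, ...)
}
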