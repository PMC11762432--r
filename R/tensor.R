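#' Build the zero-padded, doubly-masked feature tensor
#'
#' Stacks each cohort patient's annual feature vectors (entry year through
#' index year) into a right-aligned `[n, T_max, V]` array with two masks:
#' `period_mask[i, t] = 1` marks real observed years (zero-padding occupies
#' the leading slots), and `value_mask[i, t, v] = 1` marks values actually
#' recorded within a real year. Values are exactly 0 wherever the value
#' mask is 0, so "no measurement" and "measured zero" are distinguished by
#' the mask, not the value. Static features are encoded as
#' `sex` (0 = F, 1 = M) and the centred socioeconomic quintile
#' `(q - 3) / 2` (missing quintile contributes 0).
#'
#' Events dated after a patient's index year never contribute to any
#' feature (label-leakage guard).
#'
#' @param events Cleaned event table.
#' @param statics Static patient table.
#' @param schema Feature schema.
#' @param cohort Cohort table from [apply_eligibility()] (`patient_id`,
#'   `entry_year`, `index_year`).
#' @return An object of class `feature_tensor`: list with `X`,
#'   `value_mask`, `period_mask`, `S`, `variable_index`, `static_index`,
#'   `patient_ids`, `period_years`, `T_max`.
#' @export
build_tensor <- function(events, statics, schema, cohort) {
  validate_schema(schema)
  cohort <- data.table::as.data.table(cohort)
  statics <- data.table::as.data.table(statics)
  if (!all(cohort$patient_id %in% statics$patient_id))
    stop("cohort contains patients absent from the static table")

  a <- agg_history(events, schema, cohort)

  idx <- match(cohort$patient_id, statics$patient_id)
  ses <- statics$ses_quintile[idx]
  S <- cbind(
    sex = as.numeric(statics$sex[idx] == "M"),
    ses_quintile = ifelse(is.na(ses), 0, (ses - 3) / 2)
  )

  tensor <- structure(list(
    X = a$X, value_mask = a$value_mask, period_mask = a$period_mask,
    S = S, variable_index = schema$variables$variable_id,
    static_index = schema$static_variables,
    patient_ids = cohort$patient_id,
    period_years = a$period_years, T_max = a$T_max
  ), class = "feature_tensor")
  validate_tensor(tensor)
  tensor
}

#' Check the structural invariants of a feature tensor
#'
#' Asserts the mask hierarchy (`value_mask <= period_mask` elementwise),
#' that values are 0 wherever the value mask is 0, and that padding forms a
#' contiguous leading block (histories are right-aligned).
#'
#' @param tensor A `feature_tensor`.
#' @return The tensor, invisibly; errors when an invariant fails.
#' @export
validate_tensor <- function(tensor) {
  stopifnot(inherits(tensor, "feature_tensor"))
  m <- tensor$period_mask
  Mv <- tensor$value_mask
  if (any(Mv > array(m, dim = dim(Mv))))
    stop("mask hierarchy violated: value_mask > period_mask")
  if (any(tensor$X[Mv == 0] != 0))
    stop("tensor invariant violated: nonzero value at masked position")
  # right-aligned: once a period is real, all later periods are real
  if (ncol(m) > 1) {
    mono <- t(apply(m, 1, cummax))
    if (any(m != mono))
      stop("tensor invariant violated: padding is not a leading block")
  }
  if (any(rowSums(m) == 0))
    stop("tensor invariant violated: patient with no real periods")
  invisible(tensor)
}

#' @export
print.feature_tensor <- function(x, ...) {
  cat(sprintf("<feature_tensor> %d patients x %d periods x %d variables (+%d static)\n",
              dim(x$X)[1], dim(x$X)[2], dim(x$X)[3], ncol(x$S)))
  cat(sprintf("  real periods: %.1f mean, %d max\n",
              mean(rowSums(x$period_mask)), x$T_max))
  invisible(x)
}

#' End-to-end cohort tensorization
#'
#' Composes the pipeline from raw tables to model inputs: record cleaning,
#' eligibility, label derivation for the prediction window, and tensor
#' construction on the eligible patients with derivable labels.
#'
#' @param events Raw event table.
#' @param statics Static patient table.
#' @param schema Feature schema.
#' @param elig An [eligibility_config()].
#' @return A list with `tensor`, `labels` (data.table), `cohort`,
#'   `exclusions`, `cleaning_removals`, `label_omitted`.
#' @export
tensorize <- function(events, statics, schema = build_default_schema(),
                      elig = eligibility_config()) {
  cl <- clean_events(events, statics)
  el <- apply_eligibility(statics, cl$events, elig)
  lb <- derive_labels(cl$events, statics, el$cohort, elig$window)
  cohort <- el$cohort[el$cohort$patient_id %in% lb$labels$patient_id, ]
  tensor <- build_tensor(cl$events, statics, schema, cohort)
  labels <- lb$labels[match(cohort$patient_id, lb$labels$patient_id), ]
  list(tensor = tensor, labels = labels, cohort = cohort,
       exclusions = el$exclusions, cleaning_removals = cl$removals,
       label_omitted = lb$omitted)
}

#' Subset a feature tensor by patients
#'
#' Returns the tensor restricted to the given patients (ids or row
#' indices), preserving all masks and metadata.
#'
#' @param tensor A `feature_tensor`.
#' @param patients Patient ids (character) or row indices (numeric).
#' @return The subset `feature_tensor`.
#' @export
subset_tensor <- function(tensor, patients) {
  rows <- if (is.character(patients))
    match(patients, tensor$patient_ids) else as.integer(patients)
  if (anyNA(rows)) stop("unknown patients in subset")
  tensor$X <- tensor$X[rows, , , drop = FALSE]
  tensor$value_mask <- tensor$value_mask[rows, , , drop = FALSE]
  tensor$period_mask <- tensor$period_mask[rows, , drop = FALSE]
  tensor$S <- tensor$S[rows, , drop = FALSE]
  tensor$patient_ids <- tensor$patient_ids[rows]
  tensor$period_years <- tensor$period_years[rows, , drop = FALSE]
  tensor
}

#' Fit per-variable normalization statistics on the training split
#'
#' Computes, for every numeric variable (counts and continuous means), the
#' mean and population standard deviation over unmasked entries of the
#' training patients only. Binary flags and categorical modes pass through
#' untransformed.
#'
#' @param tensor A `feature_tensor`.
#' @param train_ids Patient ids of the training split.
#' @param schema The schema the tensor was built from.
#' @return A list of class `normalization_stats` (`mu`, `sigma`, `numeric`
#'   flags, `variable_index`).
#' @export
fit_normalizer <- function(tensor, train_ids, schema) {
  rows <- match(train_ids, tensor$patient_ids)
  if (anyNA(rows)) stop("train_ids not all present in tensor")
  V <- dim(tensor$X)[3]
  numeric_v <- schema_numeric(schema)
  mu <- numeric(V); sigma <- numeric(V)
  for (v in seq_len(V)) {
    if (!numeric_v[v]) next
    xv <- tensor$X[rows, , v]
    mk <- tensor$value_mask[rows, , v] == 1
    vals <- xv[mk]
    if (length(vals)) {
      mu[v] <- mean(vals)
      sigma[v] <- sqrt(mean((vals - mu[v])^2))  # population sd
    }
  }
  structure(list(mu = mu, sigma = sigma, numeric = numeric_v,
                 variable_index = tensor$variable_index),
            class = "normalization_stats")
}

#' Apply normalization statistics to a tensor
#'
#' Z-scores unmasked numeric entries with the training-split statistics;
#' masked entries remain exactly 0 (re-application never changes them), and
#' zero-variance variables are mapped to 0 (they carry no information).
#'
#' @param tensor A `feature_tensor`.
#' @param stats A `normalization_stats` from [fit_normalizer()].
#' @return The normalized `feature_tensor`.
#' @export
apply_normalizer <- function(tensor, stats) {
  stopifnot(inherits(stats, "normalization_stats"))
  if (!identical(stats$variable_index, tensor$variable_index))
    stop("normalization stats were fitted on a different schema")
  X <- tensor$X
  for (v in which(stats$numeric)) {
    s <- stats$sigma[v]
    z <- if (s > 0) (X[, , v] - stats$mu[v]) / s else 0
    X[, , v] <- z * tensor$value_mask[, , v]
  }
  tensor$X <- X
  tensor$normalized <- TRUE
  validate_tensor(tensor)
}

#' Persist / restore a feature tensor
#'
#' Writes the tensor (arrays plus variable index and any attached
#' normalization stats) as a serialized archive with the labels alongside
#' as CSV; `read_tensor()` reproduces the arrays bit-exactly.
#'
#' @param tensor A `feature_tensor`.
#' @param path File path for the archive (`.rds`).
#' @param labels Optional label table written next to the archive.
#' @return `path`, invisibly.
#' @export
write_tensor <- function(tensor, path, labels = NULL) {
  validate_tensor(tensor)
  saveRDS(tensor, path)
  if (!is.null(labels))
    write.csv(labels, sub("\\.rds$", "_labels.csv", path),
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_tensor
#' @export
read_tensor <- function(path) {
  tensor <- readRDS(path)
  validate_tensor(tensor)
  tensor
}
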