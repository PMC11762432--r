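#' Default 248-variable feature schema
#'
#' Builds the feature schema used throughout the package: eight dynamic
#' variable families totalling 246 annually-aggregated variables, plus two
#' static variables (sex assigned at birth, socioeconomic quintile), for a
#' total of 248. The family sizes mirror the primary-care feature set the
#' architecture was designed for: 60 chronic-disease occurrence flags, 37
#' frailty deficits, 67 laboratory variables (22 analytes, each contributing
#' a test count, an annual mean, and an out-of-reference-range count, plus
#' one total test count), 50 clinical measurements (23 numeric measures with
#' count and mean, 2 categorical measures with count and mode), 8
#' primary-care consultation counts, 9 hospital-admission counts, 3 billed
#' drug counts and 12 specific acute-event counts.
#'
#' Variable names are structural (family prefix + index), not clinical: the
#' schema fixes the counts, aggregation kinds and value types that drive all
#' computation, and maps each variable to the synthetic event codes that feed
#' it. Reference ranges are attached exactly to the variables that
#' participate in out-of-range counting.
#'
#' @return An object of class `ehr_schema`: a list with elements
#'   `variables` (ordered `data.table` with columns `variable_id`, `family`,
#'   `value_type`, `agg_kind`, `domain`, `code`, `ref_low`, `ref_high`),
#'   `families` (per-family sizes), `static_variables`, `total_dynamic`,
#'   `total_static`.
#' @examples
#' sc <- build_default_schema()
#' sc$total_dynamic + sc$total_static # 248
#' @export
build_default_schema <- function() {
  v <- list()

  v$chronic <- data.table::data.table(
    variable_id = sprintf("chronic_%02d", 1:60),
    family      = "chronic_disease",
    value_type  = "binary",
    agg_kind    = "flag_carry",
    domain      = "diagnosis",
    code        = sprintf("C%02d.1", 1:60),
    ref_low     = NA_real_,
    ref_high    = NA_real_
  )

  v$frailty <- data.table::data.table(
    variable_id = sprintf("frailty_%02d", 1:37),
    family      = "frailty_deficit",
    value_type  = "binary",
    agg_kind    = "flag_carry",
    domain      = "diagnosis",
    code        = sprintf("F%02d.1", 1:37),
    ref_low     = NA_real_,
    ref_high    = NA_real_
  )

  # 22 analytes x (count, mean, out-of-range count) + 1 total = 67
  lab_mid <- 80 + 5 * (1:22)
  lab_sd  <- 5 + 0.5 * (1:22)
  lab_one <- function(j, suffix, vt, ak, lo, hi) {
    data.table::data.table(
      variable_id = sprintf("lab_%02d_%s", j, suffix),
      family = "laboratory", value_type = vt, agg_kind = ak,
      domain = "lab", code = sprintf("LAB%02d", j),
      ref_low = lo, ref_high = hi
    )
  }
  labs <- data.table::rbindlist(lapply(1:22, function(j) {
    lo <- lab_mid[j] - 1.5 * lab_sd[j]
    hi <- lab_mid[j] + 1.5 * lab_sd[j]
    data.table::rbindlist(list(
      lab_one(j, "count", "count", "count", NA_real_, NA_real_),
      lab_one(j, "mean", "continuous", "mean", NA_real_, NA_real_),
      lab_one(j, "oor", "count", "oor_count", lo, hi)
    ))
  }))
  v$lab <- data.table::rbindlist(list(labs, data.table::data.table(
    variable_id = "lab_total_count", family = "laboratory",
    value_type = "count", agg_kind = "count", domain = "lab",
    code = NA_character_, ref_low = NA_real_, ref_high = NA_real_
  )))

  # 23 numeric measures x (count, mean) + 2 categorical x (count, mode) = 50
  meas <- data.table::rbindlist(lapply(1:23, function(j) {
    data.table::data.table(
      variable_id = sprintf("meas_%02d_%s", j, c("count", "mean")),
      family = "clinical_measure",
      value_type = c("count", "continuous"),
      agg_kind = c("count", "mean"),
      domain = "measure", code = sprintf("MEA%02d", j),
      ref_low = NA_real_, ref_high = NA_real_
    )
  }))
  cats <- data.table::rbindlist(lapply(1:2, function(j) {
    data.table::data.table(
      variable_id = sprintf("cat_%02d_%s", j, c("count", "mode")),
      family = "clinical_measure",
      value_type = c("count", "categorical"),
      agg_kind = c("count", "mode"),
      domain = "measure", code = sprintf("CAT%02d", j),
      ref_low = NA_real_, ref_high = NA_real_
    )
  }))
  v$measure <- data.table::rbindlist(list(meas, cats))

  v$visit <- data.table::data.table(
    variable_id = sprintf("visit_%02d", 1:8),
    family = "pc_consultation", value_type = "count", agg_kind = "count",
    domain = "visit", code = sprintf("VIS%02d", 1:8),
    ref_low = NA_real_, ref_high = NA_real_
  )

  v$admission <- data.table::data.table(
    variable_id = sprintf("adm_%02d", 1:9),
    family = "hospital_admission", value_type = "count", agg_kind = "count",
    domain = "admission", code = sprintf("ADM%02d", 1:9),
    ref_low = NA_real_, ref_high = NA_real_
  )

  v$drug <- data.table::data.table(
    variable_id = sprintf("drug_%02d", 1:3),
    family = "billed_drug", value_type = "count", agg_kind = "count",
    domain = "drug", code = c("N05BA01", "C03CA01", "A10BA02"),
    ref_low = NA_real_, ref_high = NA_real_
  )

  v$event <- data.table::data.table(
    variable_id = sprintf("event_%02d", 1:12),
    family = "specific_event", value_type = "count", agg_kind = "count",
    domain = "diagnosis", code = sprintf("S%02d.1", 1:12),
    ref_low = NA_real_, ref_high = NA_real_
  )

  variables <- data.table::rbindlist(v)
  families <- variables[, .(n_variables = .N), by = family]

  schema <- structure(list(
    variables = variables,
    families = families,
    static_variables = c("sex", "ses_quintile"),
    total_dynamic = nrow(variables),
    total_static = 2L
  ), class = "ehr_schema")
  validate_schema(schema)
  schema
}

#' Validate a feature schema
#'
#' Checks the structural invariants of an [build_default_schema()] object:
#' unique variable ids, family sizes consistent with the variable table,
#' reference ranges present exactly on out-of-range-count variables.
#'
#' @param schema An `ehr_schema` object.
#' @return The schema, invisibly; errors if an invariant is violated.
#' @export
validate_schema <- function(schema) {
  stopifnot(inherits(schema, "ehr_schema"))
  vt <- schema$variables
  if (anyDuplicated(vt$variable_id) > 0)
    stop("schema invariant violated: duplicate variable ids")
  if (schema$total_dynamic != nrow(vt))
    stop("schema invariant violated: total_dynamic != nrow(variables)")
  if (!identical(sum(schema$families$n_variables), nrow(vt)))
    stop("schema invariant violated: family sizes do not sum to variable count")
  has_range <- !is.na(vt$ref_low) & !is.na(vt$ref_high)
  if (!identical(has_range, vt$agg_kind == "oor_count"))
    stop("schema invariant violated: reference range iff out-of-range counting")
  invisible(schema)
}

#' @export
print.ehr_schema <- function(x, ...) {
  cat("<ehr_schema> ", x$total_dynamic, " dynamic + ", x$total_static,
      " static variables\n", sep = "")
  print(x$families)
  invisible(x)
}

# Variables whose annual value is known even with no relevant events that
# year (counts and carried-forward flags); mean/mode variables are unknown
# (masked) in years without a measurement.
schema_always_recorded <- function(schema) {
  schema$variables$agg_kind %in% c("count", "oor_count", "flag_carry")
}

# Numeric variables that are z-scored by the normalizer.
schema_numeric <- function(schema) {
  schema$variables$value_type %in% c("count", "continuous")
}
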