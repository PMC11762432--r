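# Bulk annual aggregation over a cohort: fills the value array, value mask
# and period mask for every (patient, history year, variable) cell.
#
# Aggregation kinds:
#   count      - number of qualifying events in the year (known zero when
#                none; always recorded in a real period)
#   oor_count  - number of lab tests outside the reference range
#   mean       - mean of recorded values; unrecorded in measurement-free years
#   mode       - most frequent category (ties -> smallest); unrecorded when
#                no measurement
#   flag_carry - once-present-always-present occurrence flag (chronic
#                disease / frailty deficits); carry-in from events before
#                cohort entry is honoured
#
# Histories are right-aligned: the index year sits at slot T_max, padding
# occupies the leading slots.
agg_history <- function(events, schema, cohort) {
  vars <- schema$variables
  V <- nrow(vars)
  n <- nrow(cohort)
  nyears <- cohort$index_year - cohort$entry_year + 1L
  T_max <- max(nyears)

  X <- array(0, dim = c(n, T_max, V))
  Mv <- array(0, dim = c(n, T_max, V))
  m <- matrix(0, n, T_max)
  years <- matrix(NA_integer_, n, T_max)
  for (i in seq_len(n)) {
    slots <- (T_max - nyears[i] + 1L):T_max
    m[i, slots] <- 1
    years[i, slots] <- cohort$entry_year[i]:cohort$index_year[i]
  }

  # variables whose value is known in every real period
  always <- which(schema_always_recorded(schema))
  for (v in always) Mv[, , v][m == 1] <- 1

  ev <- data.table::as.data.table(events)
  ev <- ev[ev$patient_id %in% cohort$patient_id, ]
  if (nrow(ev)) {
    ev[, pi := match(patient_id, cohort$patient_id)]
    ev[, year := year_of(date)]
    ev[, index_year := cohort$index_year[pi]]
    ev[, entry_year := cohort$entry_year[pi]]
    # leakage guard: nothing after the index year feeds any feature
    ev <- ev[year <= index_year]
    ev[, slot := T_max - (index_year - year)]
  }
  in_window <- function(e) e[e$year >= e$entry_year, ]

  put <- function(agg, vcol = "v") {
    if (nrow(agg) == 0) return(invisible())
    ix <- cbind(agg$pi, agg$slot, agg[[vcol]])
    X[ix] <<- agg$val
    Mv[ix] <<- 1
  }

  ## counts ---------------------------------------------------------------
  cnt_vars <- vars[vars$agg_kind == "count" & !is.na(vars$code), ]
  if (nrow(ev)) {
    e <- in_window(ev)[cnt_vars, on = c(domain = "domain", code = "code"),
                       nomatch = NULL]
    agg <- e[, .(val = as.numeric(.N)),
             by = .(pi, slot, v = match(variable_id, vars$variable_id))]
    put(agg)

    # total laboratory tests performed
    vtot <- match("lab_total_count", vars$variable_id)
    lab <- in_window(ev)[domain == "lab"]
    agg <- lab[, .(val = as.numeric(.N)), by = .(pi, slot)]
    agg[, v := vtot]
    put(agg)

    ## out-of-range lab counts --------------------------------------------
    oor_vars <- vars[vars$agg_kind == "oor_count", ]
    e <- in_window(ev)[oor_vars, on = c(domain = "domain", code = "code"),
                       nomatch = NULL]
    e <- e[!is.na(value) & (value < ref_low | value > ref_high)]
    agg <- e[, .(val = as.numeric(.N)),
             by = .(pi, slot, v = match(variable_id, vars$variable_id))]
    put(agg)

    ## means ---------------------------------------------------------------
    mean_vars <- vars[vars$agg_kind == "mean", ]
    e <- in_window(ev)[mean_vars, on = c(domain = "domain", code = "code"),
                       nomatch = NULL]
    e <- e[!is.na(value)]
    agg <- e[, .(val = mean(value)),
             by = .(pi, slot, v = match(variable_id, vars$variable_id))]
    put(agg)

    ## modes ---------------------------------------------------------------
    mode_vars <- vars[vars$agg_kind == "mode", ]
    e <- in_window(ev)[mode_vars, on = c(domain = "domain", code = "code"),
                       nomatch = NULL]
    e <- e[!is.na(value)]
    if (nrow(e)) {
      agg <- e[, {
        tab <- .SD[, .N, by = value][order(-N, value)]
        .(val = tab$value[1])
      }, by = .(pi, slot, v = match(variable_id, vars$variable_id))]
      put(agg)
    }

    ## carried-forward occurrence flags ------------------------------------
    flag_vars <- vars[vars$agg_kind == "flag_carry", ]
    # first occurrence may precede cohort entry (carry-in), so no lower
    # year filter here
    e <- ev[flag_vars, on = c(domain = "domain", code = "code"),
            nomatch = NULL]
    if (nrow(e)) {
      fy <- e[, .(first_year = min(year)),
              by = .(pi, v = match(variable_id, vars$variable_id))]
      fy[, index_year := cohort$index_year[pi]]
      fy[, from := pmax(first_year, cohort$entry_year[pi])]
      nrep <- fy$index_year - fy$from + 1L
      flag <- data.table::data.table(
        pi = rep(fy$pi, nrep), v = rep(fy$v, nrep),
        year = unlist(lapply(seq_len(nrow(fy)),
                             function(r) fy$from[r]:fy$index_year[r]),
                      use.names = FALSE)
      )
      flag[, slot := T_max - (cohort$index_year[pi] - year)]
      flag[, val := 1]
      put(flag)
    }
  }

  list(X = X, value_mask = Mv, period_mask = m, period_years = years,
       T_max = T_max)
}

#' Aggregate one patient's events for one calendar year
#'
#' Returns the annual feature vector for a single patient and year under
#' the family-specific aggregation rules: event counts (including lab tests
#' performed and tests out of reference range), annual means of numeric
#' labs/measurements, modes of categorical measurements, and
#' once-present-always-present occurrence flags for chronic diseases and
#' frailty deficits (events from earlier years carry forward). The
#' `recorded` flag is 0 exactly when no datum informs the variable that
#' year (mean/mode variables without a measurement); counts and flags are
#' known zeros and stay recorded.
#'
#' @param events Event table (all years; earlier years inform carried
#'   flags).
#' @param schema Feature schema.
#' @param patient A single patient id.
#' @param year Calendar year to aggregate.
#' @param variables Optional subset of variable ids to return; unknown ids
#'   are an error.
#' @return A `data.table` with `variable_id`, `value`, `recorded`.
#' @export
aggregate_annual <- function(events, schema, patient, year,
                             variables = NULL) {
  vars <- schema$variables
  if (!is.null(variables)) {
    unknown <- setdiff(variables, vars$variable_id)
    if (length(unknown))
      stop("variable_id not in schema: ", paste(unknown, collapse = ", "))
  }
  cohort <- data.table::data.table(
    patient_id = patient, entry_year = as.integer(year),
    index_year = as.integer(year)
  )
  a <- agg_history(events, schema, cohort)
  out <- data.table::data.table(
    variable_id = vars$variable_id,
    value = a$X[1, 1, ],
    recorded = as.integer(a$value_mask[1, 1, ])
  )
  if (!is.null(variables)) out <- out[match(variables, out$variable_id)]
  out
}
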