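#' Eligibility configuration
#'
#' Inclusion/exclusion rules of the dynamic cohort: entry at age 65+ (at
#' study start, at the 65th birthday, or at in-migration), exclusion of
#' patients aged 100+ at study start, of patients with no recorded data or
#' no primary-care visits, and of patients with less follow-up than the
#' prediction window plus one history year.
#'
#' @param study_start,study_end Calendar bounds of the study.
#' @param window Prediction horizon in years (1 or 5). The minimum
#'   follow-up is `window + 1` years (at least one history year and a full
#'   outcome window).
#' @param min_age Entry age in years (default 65).
#' @param max_age_at_start Exclusive upper age bound at study start
#'   (default 100).
#' @return A list of class `eligibility_config`.
#' @export
eligibility_config <- function(study_start = as.Date("2010-01-01"),
                               study_end = as.Date("2019-12-31"),
                               window = 1L,
                               min_age = 65,
                               max_age_at_start = 100) {
  if (!window %in% c(1L, 5L)) stop("window must be 1 or 5")
  if (min_age >= max_age_at_start) stop("min_age must be < max_age_at_start")
  structure(list(
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    window = as.integer(window),
    min_followup_years = as.integer(window) + 1L,
    min_age = min_age, max_age_at_start = max_age_at_start
  ), class = "eligibility_config")
}

#' Clean an EHR event table
#'
#' Applies the record-level cleaning rules: removes duplicate diagnoses
#' (same patient, same day, same code), diagnoses with dates inconsistent
#' with the patient's life span (before birth or after death), and
#' sex-specific diagnosis codes recorded on the wrong sex.
#'
#' @param events Long-format event `data.table` (`patient_id`, `date`,
#'   `domain`, `code`, `value`).
#' @param statics Static patient table (see [generate_cohort()]).
#' @param sex_specific_codes Optional `data.frame` with columns `code` and
#'   `sex`: each diagnosis code listed is valid only for the given sex.
#' @return A list with `events` (cleaned copy) and `removals` (named counts
#'   of rows removed per rule).
#' @export
clean_events <- function(events, statics, sex_specific_codes = NULL) {
  events <- data.table::as.data.table(events)
  statics <- data.table::as.data.table(statics)
  unknown <- setdiff(unique(events$patient_id), statics$patient_id)
  if (length(unknown))
    stop("events reference unknown patient ids: ",
         paste(head(unknown, 5), collapse = ", "))
  if (nrow(events) == 0) {
    return(list(events = events,
                removals = c(duplicate = 0L, inconsistent_date = 0L,
                             wrong_sex = 0L)))
  }
  is_diag <- events$domain == "diagnosis"

  dup <- is_diag & duplicated(data.table::data.table(
    events$patient_id, events$date, events$code, is_diag))
  # duplicated() above also keys on is_diag so non-diagnosis rows that
  # repeat (e.g. two identical visits) are legitimately kept
  dup[!is_diag] <- FALSE

  idx <- match(events$patient_id, statics$patient_id)
  birth <- statics$birth_date[idx]
  death <- statics$death_date[idx]
  bad_date <- is_diag &
    (events$date < birth | (!is.na(death) & events$date > death))

  wrong_sex <- rep(FALSE, nrow(events))
  if (!is.null(sex_specific_codes) && nrow(sex_specific_codes)) {
    m <- match(events$code, sex_specific_codes$code)
    wrong_sex <- is_diag & !is.na(m) &
      statics$sex[idx] != sex_specific_codes$sex[m]
  }

  removals <- c(duplicate = sum(dup),
                inconsistent_date = sum(bad_date & !dup),
                wrong_sex = sum(wrong_sex & !dup & !bad_date))
  list(events = events[!(dup | bad_date | wrong_sex), ],
       removals = removals)
}

#' Apply dynamic-cohort eligibility rules
#'
#' Determines the included patients and their follow-up bounds under the
#' dynamic-cohort design: entry at `max(study start, 65th birthday,
#' registry entry)`, exit at `min(study end, registry exit, death)`.
#' Patients are excluded, in order, when they have no events at all, no
#' primary-care visit events inside the study window, are aged
#' `max_age_at_start` or older at study start, never accrue follow-up
#' inside the window, or have fewer than `window + 1` follow-up years.
#'
#' @param statics Static patient table.
#' @param events Cleaned event table.
#' @param cfg An [eligibility_config()].
#' @return A list with `cohort` (data.table: `patient_id`, `entry_year`,
#'   `exit_year`, `index_year = exit_year - window`) and `exclusions`
#'   (named counts per rule).
#' @export
apply_eligibility <- function(statics, events, cfg) {
  stopifnot(inherits(cfg, "eligibility_config"))
  statics <- data.table::as.data.table(statics)
  events <- data.table::as.data.table(events)
  y0 <- year_of(cfg$study_start); y1 <- year_of(cfg$study_end)

  age_at_start <- as.numeric(cfg$study_start - statics$birth_date) / 365.25
  turns_min <- statics$birth_date + round(cfg$min_age * 365.25)
  entry_year <- pmax(y0, year_of(turns_min),
                     year_of(statics$registry_entry_date))
  exit_date <- pmin(statics$registry_exit_date, cfg$study_end, na.rm = TRUE)
  exit_date <- pmin(exit_date, statics$death_date, na.rm = TRUE)
  exit_year <- year_of(exit_date)

  has_events <- statics$patient_id %in% unique(events$patient_id)
  vis <- events[events$domain == "visit" &
                  events$date >= cfg$study_start &
                  events$date <= cfg$study_end, ]
  has_visits <- statics$patient_id %in% unique(vis$patient_id)

  excl <- rep(NA_character_, nrow(statics))
  excl[!has_events] <- "no_data"
  excl[is.na(excl) & !has_visits] <- "no_visits"
  excl[is.na(excl) & age_at_start >= cfg$max_age_at_start] <- "age_at_start"
  excl[is.na(excl) & (entry_year > y1 | exit_year < entry_year)] <-
    "no_followup_in_window"
  excl[is.na(excl) &
         (exit_year - entry_year + 1L) < cfg$min_followup_years] <-
    "short_followup"

  keep <- is.na(excl)
  exclusions <- table(factor(excl, levels = c(
    "no_data", "no_visits", "age_at_start", "no_followup_in_window",
    "short_followup")))
  cohort <- data.table::data.table(
    patient_id = statics$patient_id[keep],
    entry_year = entry_year[keep],
    exit_year = exit_year[keep],
    index_year = exit_year[keep] - cfg$window
  )
  list(cohort = cohort,
       exclusions = setNames(as.integer(exclusions), names(exclusions)))
}

#' Derive outcome labels for a prediction window
#'
#' Labels each patient's outcome status in the half-open interval
#' `(end of index year, end of index year + window]`: all-cause mortality
#' from the death date, nursing-home admission from any diagnosis coded
#' `Z59.3`, and home-care need from any diagnosis code starting with `Z74`.
#' Patients whose follow-up ends inside the window without a death are
#' omitted (their window is not fully observed) and counted.
#'
#' @param events Cleaned event table.
#' @param statics Static patient table.
#' @param index `data.frame` with `patient_id` and `index_year` (e.g. the
#'   `cohort` element of [apply_eligibility()]).
#' @param window Prediction horizon in years.
#' @return A list with `labels` (data.table: `patient_id`, `index_year`,
#'   `mortality`, `nursing_home`, `home_care`) and `omitted` (count of
#'   patients without a fully observed window).
#' @export
derive_labels <- function(events, statics, index, window) {
  index <- data.table::as.data.table(index)[, .(patient_id, index_year)]
  statics <- data.table::as.data.table(statics)
  events <- data.table::as.data.table(events)

  idx <- match(index$patient_id, statics$patient_id)
  win_start <- as.Date(sprintf("%d-12-31", index$index_year))
  win_end <- as.Date(sprintf("%d-12-31", index$index_year + window))

  death <- statics$death_date[idx]
  mortality <- !is.na(death) & death > win_start & death <= win_end

  # follow-up must cover the window unless the patient dies inside it
  fu_end <- pmin(statics$registry_exit_date[idx], na.rm = TRUE)
  observed <- mortality |
    (year_of(fu_end) >= index$index_year + window)

  code_hits <- function(pattern) {
    hit <- events[events$domain == "diagnosis" &
                    startsWith(events$code, pattern), ]
    m <- match(hit$patient_id, index$patient_id)
    ok <- !is.na(m) & hit$date > win_start[m] & hit$date <= win_end[m]
    index$patient_id %in% hit$patient_id[ok]
  }
  nursing_home <- code_hits("Z59.3")
  home_care <- code_hits("Z74")

  labels <- data.table::data.table(
    patient_id = index$patient_id,
    index_year = index$index_year,
    mortality = as.integer(mortality),
    nursing_home = as.integer(nursing_home),
    home_care = as.integer(home_care)
  )[observed]
  list(labels = labels, omitted = sum(!observed))
}
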