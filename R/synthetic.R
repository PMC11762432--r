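#' Synthetic cohort configuration
#'
#' Bundles the parameters of the seeded synthetic EHR generator: a dynamic
#' cohort of adults aged 65+ followed over a calendar window, with
#' heterogeneous primary-care visit intensity driving missingness, and three
#' binary outcomes (death, nursing-home admission coded Z59.3, home-care
#' need coded Z74*) drawn from a known recency-weighted logistic risk model
#' so that signal recovery by the model and its attention maps is testable.
#'
#' @param n_patients Number of patients to simulate.
#' @param study_start,study_end Calendar bounds of the study window
#'   (defaults 2010-01-01 to 2019-12-31).
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#' @param visit_rate_range Lower/upper bound of the per-patient yearly
#'   Poisson visit intensity (uniform across patients).
#' @param arrival_fraction Fraction of patients already aged 65+ at study
#'   start who instead in-migrate at a uniform time during the window.
#' @param dropout_rate Per-year probability of loss to follow-up.
#' @param window Prediction horizon in years (1 or 5); outcomes are drawn
#'   for the window after each patient's index year (last follow-up year
#'   minus the window).
#' @param risk_spec `data.frame` with columns `variable_id`, `effect_size`,
#'   `recency_profile` (`"last_year_only"`, `"uniform"` or `"decaying"`):
#'   the planted risk structure. Effects act on population-standardized
#'   annual feature values. `NULL` plants no signal (outcomes at base rate).
#' @param outcome_base_rates Named probabilities for `mortality`,
#'   `nursing_home`, `home_care` at zero linear predictor.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 1000L,
                             study_start = as.Date("2010-01-01"),
                             study_end = as.Date("2019-12-31"),
                             seed = 1L,
                             visit_rate_range = c(0.5, 8),
                             arrival_fraction = 0.10,
                             dropout_rate = 0.02,
                             window = 1L,
                             risk_spec = default_risk_spec(),
                             outcome_base_rates = c(mortality = 0.24,
                                                    nursing_home = 0.09,
                                                    home_care = 0.14)) {
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (!is.numeric(n_patients) || n_patients <= 0)
    stop("n_patients must be a positive integer")
  if (study_start >= study_end) stop("study_start must precede study_end")
  if (!is.null(risk_spec)) {
    risk_spec <- as.data.frame(risk_spec)
    stopifnot(all(c("variable_id", "effect_size", "recency_profile") %in%
                    names(risk_spec)))
    if (any(!is.finite(risk_spec$effect_size)))
      stop("effect sizes must be finite")
    if (!all(risk_spec$recency_profile %in%
             c("last_year_only", "uniform", "decaying")))
      stop("unknown recency_profile")
  }
  stopifnot(all(outcome_base_rates > 0 & outcome_base_rates < 1),
            all(c("mortality", "nursing_home", "home_care") %in%
                  names(outcome_base_rates)))
  if (!window %in% c(1L, 5L)) stop("window must be 1 or 5")
  structure(list(
    n_patients = as.integer(n_patients), study_start = study_start,
    study_end = study_end, seed = as.integer(seed),
    visit_rate_range = visit_rate_range,
    arrival_fraction = arrival_fraction, dropout_rate = dropout_rate,
    window = as.integer(window), risk_spec = risk_spec,
    outcome_base_rates = outcome_base_rates
  ), class = "synthetic_config")
}

#' Default planted risk specification
#'
#' Three strongly-weighted acute variables (two specific-event counts and
#' one hospital-admission count) acting through the last history year only.
#' Acute counts are drawn independently across years, so this signal is
#' invisible in a patient's first observed year: it is recoverable by a
#' longitudinal model but not by cross-sectional baselines, and it
#' concentrates time-level attention on the most recent period.
#'
#' @return A `data.frame` with columns `variable_id`, `effect_size`,
#'   `recency_profile`.
#' @export
default_risk_spec <- function() {
  data.frame(
    variable_id = c("event_01", "event_02", "adm_01"),
    effect_size = c(2.0, 2.0, 2.0),
    recency_profile = "last_year_only",
    stringsAsFactors = FALSE
  )
}

rand_date_in_year <- function(year) {
  start <- as.Date(sprintf("%d-01-01", year))
  start + floor(runif(length(year)) * 365)
}

year_of <- function(d) as.integer(format(d, "%Y"))

#' Generate a synthetic dynamic cohort
#'
#' Simulates a long-format EHR event table, a static patient table and the
#' planted outcome truth under the dynamic-cohort design: patients aged 65+
#' at study start enter at baseline (a configurable fraction in-migrate
#' later), younger patients enter at their 65th birthday, and follow-up
#' ends at loss, death or study end. Per-patient yearly visit counts follow
#' a patient-specific Poisson intensity; laboratory tests and clinical
#' measurements are only recorded in years with at least one visit, which
#' creates the value-level missingness the model's masks absorb. Outcomes
#' are drawn once per patient from a logistic model on recency-weighted,
#' population-standardized planted features evaluated at the index year
#' (last follow-up year minus the prediction window); outcome events (death
#' date, Z59.3 and Z74.* diagnoses) are placed uniformly inside the window.
#'
#' @param cfg A [synthetic_config()].
#' @param schema A feature schema from [build_default_schema()].
#' @return A list with `events` (data.table: patient_id, date, domain,
#'   code, value), `statics` (data.table: patient_id, birth_date, sex,
#'   ses_quintile, registry_entry_date, registry_exit_date, death_date) and
#'   `truth` (planted risk echo: risk_spec, per-patient index year, linear
#'   predictor, outcome probabilities and drawn outcomes).
#' @export
generate_cohort <- function(cfg, schema = build_default_schema()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  validate_schema(schema)
  set.seed(cfg$seed)
  n <- cfg$n_patients
  y0 <- year_of(cfg$study_start); y1 <- year_of(cfg$study_end)

  pid <- sprintf("P%06d", seq_len(n))

  ## --- statics -----------------------------------------------------------
  age0 <- runif(n, 55, 97)                       # age at study start
  birth_date <- cfg$study_start - round(age0 * 365.25)
  sex <- ifelse(runif(n) < 0.56, "F", "M")
  ses_p <- c(0.132, 0.302, 0.334, 0.190, 0.042)
  ses <- sample.int(5L, n, replace = TRUE, prob = ses_p / sum(ses_p))
  ses[runif(n) < 0.022] <- NA_integer_

  turns65 <- birth_date + round(65 * 365.25)
  entry_year <- pmax(y0, year_of(turns65))
  inmig <- age0 >= 65 & runif(n) < cfg$arrival_fraction
  entry_year[inmig] <- entry_year[inmig] +
    sample.int(y1 - y0 + 1L, sum(inmig), replace = TRUE) - 1L
  # loss to follow-up: geometric number of completed years after entry
  loss_after <- rgeom(n, cfg$dropout_rate)
  exit_year <- pmin(entry_year + loss_after, y1)
  active <- entry_year <= y1

  lambda <- runif(n, cfg$visit_rate_range[1], cfg$visit_rate_range[2])

  ## --- patient-year grid -------------------------------------------------
  ny <- ifelse(active, exit_year - entry_year + 1L, 0L)
  grid <- data.table::data.table(
    pi = rep(seq_len(n), ny),
    year = unlist(lapply(which(active),
                         function(i) entry_year[i]:exit_year[i]),
                  use.names = FALSE)
  )
  grid[, patient_id := pid[pi]]

  ev <- list()
  add_rows <- function(pi_idx, year, domain, code, value = NA_real_) {
    if (length(pi_idx) == 0) return(NULL)
    data.table::data.table(
      patient_id = pid[pi_idx], date = rand_date_in_year(year),
      domain = domain, code = code, value = value
    )
  }

  ## --- visits (8 types, decreasing frequency) ----------------------------
  visits <- rpois(nrow(grid), lambda[grid$pi])
  grid[, n_visits := visits]
  vrow <- rep.int(seq_len(nrow(grid)), visits)
  vis_p <- exp(-0.4 * (0:7))
  ev$visit <- add_rows(grid$pi[vrow], grid$year[vrow], "visit",
                       sprintf("VIS%02d", sample.int(8L, length(vrow),
                               replace = TRUE, prob = vis_p / sum(vis_p))))

  ## --- laboratory tests (only in years with >= 1 visit) ------------------
  vars <- schema$variables
  lab_rows <- list()
  lab_offset <- matrix(rnorm(n * 22), n, 22)   # patient-level analyte shift
  for (j in 1:22) {
    rr <- vars[vars$agg_kind == "oor_count" &
                 vars$code == sprintf("LAB%02d", j), ]
    mid <- (rr$ref_low + rr$ref_high) / 2
    sdj <- (rr$ref_high - rr$ref_low) / 3
    qj <- 0.5 * exp(-0.18 * (j - 1))
    ntest <- rbinom(nrow(grid), size = pmin(grid$n_visits, 4L), prob = qj)
    trow <- rep.int(seq_len(nrow(grid)), ntest)
    if (length(trow)) {
      vals <- rnorm(length(trow),
                    mean = mid + 0.45 * sdj * lab_offset[grid$pi[trow], j],
                    sd = 0.9 * sdj)
      lab_rows[[j]] <- add_rows(grid$pi[trow], grid$year[trow], "lab",
                                sprintf("LAB%02d", j), vals)
    }
  }
  ev$lab <- data.table::rbindlist(lab_rows)

  ## --- clinical measurements ---------------------------------------------
  meas_rows <- list()
  for (j in 1:23) {
    nm <- rbinom(nrow(grid), size = pmin(grid$n_visits, 3L), prob = 0.35)
    mrow <- rep.int(seq_len(nrow(grid)), nm)
    if (length(mrow)) {
      vals <- rnorm(length(mrow), mean = 50 + 2 * j, sd = 3 + 0.2 * j)
      meas_rows[[j]] <- add_rows(grid$pi[mrow], grid$year[mrow], "measure",
                                 sprintf("MEA%02d", j), vals)
    }
  }
  for (j in 1:2) {
    nc <- rbinom(nrow(grid), size = pmin(grid$n_visits, 2L), prob = 0.3)
    crow <- rep.int(seq_len(nrow(grid)), nc)
    if (length(crow)) {
      meas_rows[[23 + j]] <- add_rows(grid$pi[crow], grid$year[crow],
                                      "measure", sprintf("CAT%02d", j),
                                      sample.int(3L, length(crow),
                                                 replace = TRUE))
    }
  }
  ev$measure <- data.table::rbindlist(meas_rows)

  ## --- chronic diseases & frailty deficits (onset + re-records) ----------
  onset_family <- function(codes, p_onset) {
    rows <- list()
    for (k in seq_along(codes)) {
      off <- rgeom(n, p_onset[k])
      oy <- entry_year + off
      has <- active & oy <= exit_year
      if (!any(has)) next
      idx <- which(has)
      rows[[length(rows) + 1L]] <-
        add_rows(idx, oy[idx], "diagnosis", codes[k])
      # re-recording in later years (persistence noise, not new information)
      later <- grid[grid$year > oy[grid$pi], ]
      later <- later[later$pi %in% idx & runif(nrow(later)) < 0.15, ]
      # restrict to this condition's carriers
      if (nrow(later))
        rows[[length(rows) + 1L]] <-
          add_rows(later$pi, later$year, "diagnosis", codes[k])
    }
    data.table::rbindlist(rows)
  }
  ev$chronic <- onset_family(sprintf("C%02d.1", 1:60),
                             0.002 + 0.018 * (1:60) / 60)
  ev$frailty <- onset_family(sprintf("F%02d.1", 1:37),
                             0.001 + 0.015 * (1:37) / 37)

  ## --- acute specific events, admissions, billed drugs -------------------
  pois_family <- function(codes, rates, domain) {
    rows <- list()
    for (k in seq_along(codes)) {
      cnt <- rpois(nrow(grid), rates[k])
      rowi <- rep.int(seq_len(nrow(grid)), cnt)
      if (length(rowi))
        rows[[k]] <- add_rows(grid$pi[rowi], grid$year[rowi], domain,
                              codes[k])
    }
    data.table::rbindlist(rows)
  }
  ev$event <- pois_family(sprintf("S%02d.1", 1:12),
                          0.3 * exp(-0.15 * (0:11)), "diagnosis")
  ev$adm <- pois_family(sprintf("ADM%02d", 1:9),
                        0.25 * exp(-0.3 * (0:8)), "admission")
  ev$drug <- pois_family(c("N05BA01", "C03CA01", "A10BA02"),
                         c(2, 1, 0.5), "drug")

  events <- data.table::rbindlist(ev, use.names = TRUE)

  # inject same-day duplicate diagnoses (cleaning-rule fodder)
  diag_idx <- which(events$domain == "diagnosis")
  dup <- diag_idx[runif(length(diag_idx)) < 0.01]
  if (length(dup)) events <- rbind(events, events[dup])

  ## --- planted outcomes --------------------------------------------------
  index_year <- exit_year - cfg$window
  has_index <- active & index_year >= entry_year
  lin <- planted_linear_predictor(events, schema, cfg, pid, entry_year,
                                  index_year, has_index)

  rates <- cfg$outcome_base_rates
  outcomes <- c("mortality", "nursing_home", "home_care")
  probs <- sapply(outcomes, function(o) plogis(qlogis(rates[[o]]) + lin))
  probs[!has_index, ] <- NA_real_
  draws <- matrix(NA, n, 3, dimnames = list(pid, outcomes))
  draws[has_index, ] <- runif(sum(has_index) * 3) <
    probs[has_index, ]

  death_date <- as.Date(rep(NA, n))
  died <- !is.na(draws[, "mortality"]) & draws[, "mortality"] == 1
  if (any(died)) {
    dy <- index_year[died] +
      sample.int(cfg$window, sum(died), replace = TRUE)
    death_date[died] <- rand_date_in_year(dy)
    exit_year[died] <- dy
  }

  outcome_rows <- function(flag, codes) {
    sel <- which(!is.na(draws[, flag]) & draws[, flag] == 1)
    if (!length(sel)) return(NULL)
    oy <- index_year[sel] + sample.int(cfg$window, length(sel),
                                       replace = TRUE)
    d <- rand_date_in_year(oy)
    dd <- death_date[sel]
    clamp <- !is.na(dd) & d > dd
    d[clamp] <- dd[clamp]
    data.table::data.table(
      patient_id = pid[sel], date = d, domain = "diagnosis",
      code = sample(codes, length(sel), replace = TRUE), value = NA_real_
    )
  }
  events <- data.table::rbindlist(list(
    events,
    outcome_rows("nursing_home", "Z59.3"),
    outcome_rows("home_care", c("Z74.0", "Z74.1", "Z74.3", "Z74.8"))
  ), use.names = TRUE)

  # deaths truncate the record
  dd_all <- death_date[match(events$patient_id, pid)]
  events <- events[is.na(dd_all) | events$date <= dd_all, ]

  data.table::setorder(events, patient_id, date, domain, code, value,
                       na.last = TRUE)

  registry_exit <- pmin(as.Date(sprintf("%d-12-31", exit_year)),
                        cfg$study_end)
  registry_exit[!is.na(death_date)] <- death_date[!is.na(death_date)]
  statics <- data.table::data.table(
    patient_id = pid, birth_date = birth_date, sex = sex,
    ses_quintile = ses,
    registry_entry_date = pmax(as.Date(sprintf("%d-01-01", entry_year)),
                               pmin(turns65, cfg$study_end)),
    registry_exit_date = registry_exit,
    death_date = death_date
  )

  truth <- list(
    risk_spec = cfg$risk_spec,
    outcome_base_rates = rates,
    window = cfg$window,
    index_year = setNames(ifelse(has_index, index_year, NA_integer_), pid),
    linear_predictor = setNames(lin, pid),
    outcome_probs = probs,
    outcomes = draws
  )
  list(events = events, statics = statics, truth = truth)
}

# Recency weight of history year t for an index year I.
recency_weights <- function(years, index_year, profile) {
  lag <- index_year - years
  switch(profile,
    last_year_only = as.numeric(lag == 0),
    uniform = rep(1 / length(years), length(years)),
    decaying = 0.5^lag,
    stop("unknown recency_profile: ", profile)
  )
}

# Linear predictor of the planted logistic risk model: for each planted
# variable, the recency-weighted sum of population-standardized annual
# values over the patient's history up to the index year. Count-type
# variables contribute known zeros in event-free years.
planted_linear_predictor <- function(events, schema, cfg, pid, entry_year,
                                     index_year, has_index) {
  n <- length(pid)
  lin <- numeric(n)
  rs <- cfg$risk_spec
  if (is.null(rs) || nrow(rs) == 0) return(lin)
  vars <- schema$variables
  unknown <- setdiff(rs$variable_id, vars$variable_id)
  if (length(unknown))
    stop("risk_spec variables not in schema: ",
         paste(unknown, collapse = ", "))

  # dense history grid (known zeros included) for patients with an index
  hp <- which(has_index)
  nh <- index_year[hp] - entry_year[hp] + 1L
  hist <- data.table::data.table(
    pi = rep(hp, nh),
    year = unlist(lapply(hp, function(i) entry_year[i]:index_year[i]),
                  use.names = FALSE)
  )
  hist[, lag := index_year[pi] - year]
  ev_pi <- match(events$patient_id, pid)
  ev_year <- year_of(events$date)

  for (r in seq_len(nrow(rs))) {
    vr <- vars[vars$variable_id == rs$variable_id[r], ]
    if (!vr$agg_kind %in% c("count", "flag_carry"))
      stop("planted variables must be count or carried-flag kind, got: ",
           vr$agg_kind)
    sel <- events$domain == vr$domain & events$code == vr$code
    cnt <- data.table::data.table(pi = ev_pi[sel], year = ev_year[sel])
    cnt <- cnt[, .(x = as.numeric(.N)), by = .(pi, year)]
    h <- data.table::copy(hist)
    h[cnt, x := i.x, on = c("pi", "year")]
    h[is.na(x), x := 0]
    if (vr$agg_kind == "flag_carry")
      h[, x := as.numeric(cumsum(x) > 0), by = pi]
    prof <- rs$recency_profile[r]
    h[, w := switch(prof,
                    last_year_only = as.numeric(lag == 0),
                    uniform = 1 / .N,
                    decaying = 0.5^lag), by = pi]
    mu <- mean(h$x); sg <- sd(h$x)
    if (!is.finite(sg) || sg == 0) sg <- 1
    # center by mu * sum(w) so that zero effect keeps the base rate
    agg <- h[, .(contrib = sum(w * (x - mu)) / sg), by = pi]
    lin[agg$pi] <- lin[agg$pi] + rs$effect_size[r] * agg$contrib
  }
  lin
}

#' Write / read a cohort's event and static tables
#'
#' Persists the long-format event table and the static patient table as
#' CSV (ISO-8601 dates) or as columnar binary (Parquet, via the `arrow`
#' package).
#'
#' @param events,statics Tables as returned by [generate_cohort()].
#' @param dir Output directory (created).
#' @param format `"csv"` or `"parquet"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(events, statics, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "csv") {
    data.table::fwrite(events, file.path(dir, "events.csv"))
    data.table::fwrite(statics, file.path(dir, "statics.csv"))
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the arrow package is required for parquet output")
    arrow::write_parquet(events, file.path(dir, "events.parquet"))
    arrow::write_parquet(statics, file.path(dir, "statics.parquet"))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  if (format == "csv") {
    events <- data.table::fread(file.path(dir, "events.csv"))
    events$date <- as.Date(events$date)
    statics <- data.table::fread(file.path(dir, "statics.csv"))
    for (cc in c("birth_date", "registry_entry_date", "registry_exit_date",
                 "death_date"))
      statics[[cc]] <- as.Date(statics[[cc]])
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the arrow package is required for parquet input")
    events <- data.table::as.data.table(
      arrow::read_parquet(file.path(dir, "events.parquet")))
    statics <- data.table::as.data.table(
      arrow::read_parquet(file.path(dir, "statics.parquet")))
  }
  list(events = events, statics = statics)
}

#' Attention recovery of the planted risk structure
#'
#' Compares a trained model's population attention map with the generator's
#' planted truth: the fraction of planted variables ranked in the top decile
#' of population variable attention, and the Spearman rank correlation
#' between planted effect sizes and the variables' mean attention.
#'
#' @param truth The `truth` element returned by [generate_cohort()].
#' @param pop_map A [population_map()] built on test-set attention.
#' @return A list with `recovery_fraction`, `rank_correlation`,
#'   `top_decile_size`, `planted`, and `flag` (non-`NULL` when the truth
#'   plants no variables, in which case recovery is undefined).
#' @export
planted_signal_report <- function(truth, pop_map) {
  stopifnot(inherits(pop_map, "population_map"))
  rs <- truth$risk_spec
  if (is.null(rs) || nrow(rs) == 0) {
    return(list(recovery_fraction = NA_real_, rank_correlation = NA_real_,
                top_decile_size = NA_integer_, planted = character(0),
                flag = "no planted variables; recovery undefined"))
  }
  rank_tab <- pop_map$variable_ranking
  if (!all(rs$variable_id %in% rank_tab$variable_id))
    stop("planted variables missing from the attention map's schema")
  k <- as.integer(ceiling(nrow(rank_tab) / 10))
  top <- rank_tab$variable_id[seq_len(k)]
  frac <- mean(rs$variable_id %in% top)
  mean_att <- rank_tab$mean_alpha[match(rs$variable_id,
                                        rank_tab$variable_id)]
  rc <- if (nrow(rs) >= 2 && sd(rs$effect_size) > 0 && sd(mean_att) > 0) {
    cor(rs$effect_size, mean_att, method = "spearman")
  } else NA_real_
  list(recovery_fraction = frac, rank_correlation = rc,
       top_decile_size = k, planted = rs$variable_id, flag = NULL)
}
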