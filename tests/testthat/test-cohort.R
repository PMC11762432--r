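micro_statics <- function() {
  data.table::data.table(
    patient_id = c("A", "B", "C"),
    birth_date = as.Date(c("1940-06-01", "1909-06-01", "1947-03-01")),
    sex = c("F", "M", "F"),
    ses_quintile = c(2L, NA, 5L),
    registry_entry_date = as.Date(c("2010-01-01", "2010-01-01",
                                    "2012-03-01")),
    registry_exit_date = as.Date(c("2019-12-31", "2019-12-31",
                                   "2019-12-31")),
    death_date = as.Date(c(NA, NA, "2017-06-15"))
  )
}

test_that("duplicate same-day diagnoses collapse to one row", {
  st <- micro_statics()
  ev <- data.table::data.table(
    patient_id = c("A", "A", "A"),
    date = as.Date(c("2014-02-01", "2014-02-01", "2014-02-02")),
    domain = "diagnosis", code = "Z74.1", value = NA_real_)
  cl <- clean_events(ev, st)
  expect_identical(nrow(cl$events), 2L)
  expect_identical(unname(cl$removals["duplicate"]), 1L)
})

test_that("diagnoses dated outside the lifespan are removed", {
  st <- micro_statics()
  ev <- data.table::data.table(
    patient_id = c("C", "C", "A"),
    date = as.Date(c("2018-01-01",   # after C's death
                     "2015-01-01",   # fine
                     "1939-01-01")), # before A's birth
    domain = "diagnosis", code = c("C01.1", "C01.1", "C02.1"),
    value = NA_real_)
  cl <- clean_events(ev, st)
  expect_identical(nrow(cl$events), 1L)
  expect_identical(unname(cl$removals["inconsistent_date"]), 2L)
})

test_that("sex-specific codes on the wrong sex are removed", {
  st <- micro_statics()
  ev <- data.table::data.table(
    patient_id = c("A", "B"), date = as.Date("2015-01-01"),
    domain = "diagnosis", code = "C05.1", value = NA_real_)
  cl <- clean_events(ev, st,
                     sex_specific_codes = data.frame(code = "C05.1",
                                                     sex = "F"))
  expect_identical(cl$events$patient_id, "A")
  expect_identical(unname(cl$removals["wrong_sex"]), 1L)
})

test_that("empty event table cleans to empty with zero removals", {
  cl <- clean_events(data.table::data.table(
    patient_id = character(), date = as.Date(character()),
    domain = character(), code = character(), value = numeric()),
    micro_statics())
  expect_identical(nrow(cl$events), 0L)
  expect_true(all(cl$removals == 0))
})

test_that("unknown patient ids in events are an error", {
  ev <- data.table::data.table(patient_id = "ZZZ",
                               date = as.Date("2015-01-01"),
                               domain = "visit", code = "VIS01",
                               value = NA_real_)
  expect_error(clean_events(ev, micro_statics()), "unknown patient")
})

visits_for <- function(ids, years) {
  data.table::rbindlist(lapply(seq_along(ids), function(i)
    data.table::data.table(patient_id = ids[i],
                           date = as.Date(sprintf("%d-06-01", years[[i]])),
                           domain = "visit", code = "VIS01",
                           value = NA_real_)))
}

test_that("eligibility excludes centenarians, the event-free and the visit-free", {
  st <- micro_statics()   # B is 100.6 years old at study start
  ev <- visits_for(c("A", "B"), list(2010:2019, 2010:2019))
  ev <- rbind(ev, data.table::data.table(
    patient_id = "C", date = as.Date("2015-01-01"),
    domain = "diagnosis", code = "C01.1", value = NA_real_))
  el <- apply_eligibility(st, ev, eligibility_config(window = 1L))
  expect_identical(el$cohort$patient_id, "A")
  expect_identical(unname(el$exclusions["age_at_start"]), 1L)  # B
  expect_identical(unname(el$exclusions["no_visits"]), 1L)     # C
  el2 <- apply_eligibility(st, ev[ev$patient_id != "A", ],
                           eligibility_config(window = 1L))
  expect_identical(unname(el2$exclusions["no_data"]), 1L)      # A
})

test_that("a patient turning 65 mid-study enters that year", {
  st <- micro_statics()[1]
  st$birth_date <- as.Date("1949-05-10")     # turns 65 in 2014
  ev <- visits_for("A", list(2010:2019))
  el <- apply_eligibility(st, ev, eligibility_config(window = 1L))
  expect_identical(el$cohort$entry_year, 2014L)
  expect_identical(el$cohort$exit_year, 2019L)
  expect_identical(el$cohort$index_year, 2018L)
})

test_that("short follow-up is eliminated per prediction window", {
  st <- micro_statics()[1]
  ev <- visits_for("A", list(2010:2014))
  st$registry_exit_date <- as.Date("2014-12-31")
  el1 <- apply_eligibility(st, ev, eligibility_config(window = 1L))
  expect_identical(nrow(el1$cohort), 1L)     # 5 years >= 2: kept
  el5 <- apply_eligibility(st, ev, eligibility_config(window = 5L))
  expect_identical(nrow(el5$cohort), 0L)     # 5 years < 6: eliminated
  expect_identical(unname(el5$exclusions["short_followup"]), 1L)
  st$registry_exit_date <- as.Date("2015-12-31")
  el5b <- apply_eligibility(st, visits_for("A", list(2010:2015)),
                            eligibility_config(window = 5L))
  expect_identical(nrow(el5b$cohort), 1L)    # 6 years >= 6: kept
  expect_identical(el5b$cohort$index_year, 2010L)
})

test_that("labels follow the outcome codes inside the window", {
  st <- micro_statics()
  idx <- data.table::data.table(patient_id = c("A", "B"),
                                index_year = c(2015L, 2015L))
  ev <- data.table::data.table(
    patient_id = c("A", "B"),
    date = as.Date(c("2016-09-20",    # 9 months after index-year end
                     "2016-03-01")),
    domain = "diagnosis", code = c("Z74.1", "Z59.3"), value = NA_real_)
  lb <- derive_labels(ev, st, idx, window = 1L)
  expect_identical(lb$labels$home_care, c(1L, 0L))
  expect_identical(lb$labels$nursing_home, c(0L, 1L))
  expect_identical(lb$labels$mortality, c(0L, 0L))
})

test_that("event-free survivors get all-zero labels; deaths are labeled", {
  st <- micro_statics()
  idx <- data.table::data.table(patient_id = c("A", "C"),
                                index_year = c(2015L, 2016L))
  ev <- data.table::data.table(patient_id = character(),
                               date = as.Date(character()),
                               domain = character(), code = character(),
                               value = numeric())
  lb <- derive_labels(ev, st, idx, window = 1L)
  expect_identical(unlist(lb$labels[lb$labels$patient_id == "A",
                                    c("mortality", "nursing_home",
                                      "home_care")], use.names = FALSE),
                   c(0L, 0L, 0L))
  # C dies 2017-06-15, inside (end of 2016, end of 2017]
  expect_identical(lb$labels$mortality[lb$labels$patient_id == "C"], 1L)
})

test_that("outcome events outside the window do not label", {
  st <- micro_statics()
  idx <- data.table::data.table(patient_id = "A", index_year = 2015L)
  ev <- data.table::data.table(
    patient_id = "A", date = as.Date(c("2015-06-01", "2018-06-01")),
    domain = "diagnosis", code = "Z74.0", value = NA_real_)
  lb <- derive_labels(ev, st, idx, window = 1L)
  expect_identical(lb$labels$home_care, 0L)
})
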