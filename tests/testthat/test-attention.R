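att_fixture <- function(B = 12, T_ = 5, V = 9, seed = 91) {
  t <- random_tensor(B, T_, V, seed = seed)
  pp <- random_params("GRU", U = 4L, V = V, seed = seed + 1L)
  fw <- forward_att(pp, t)
  list(t = t, att = fw)
}

test_that("a one-patient population map equals that patient's attention", {
  fx <- att_fixture()
  one <- subset_tensor(fx$t, 1L)
  att1 <- list(alpha = fx$att$alpha[1, , , drop = FALSE],
               beta = fx$att$beta[1, , drop = FALSE])
  pm <- population_map(att1, one)
  for (tt in which(one$period_mask[1, ] == 1)) {
    expect_equal(pm$mean_alpha[tt, ], fx$att$alpha[1, tt, ])
    expect_equal(pm$mean_beta[tt], fx$att$beta[1, tt])
  }
})

test_that("uniform attention ties resolve in schema order with a flag", {
  t <- random_tensor(4, 3, 15, seed = 95, p_missing = 0)
  att <- list(alpha = array(1 / 15, dim = c(4, 3, 15)) *
                array(t$period_mask, dim = c(4, 3, 15)),
              beta = t$period_mask / rowSums(t$period_mask))
  pm <- population_map(att, t)
  expect_true(pm$tie_flag)
  expect_identical(pm$top_variables, t$variable_index[1:10])
})

test_that("population ranking averages only over real periods", {
  fx <- att_fixture()
  pm <- population_map(fx$att, fx$t)
  V <- dim(fx$att$alpha)[3]
  w <- fx$t$period_mask
  manual <- vapply(seq_len(V), function(v)
    sum(fx$att$alpha[, , v] * w) / sum(w), numeric(1))
  ord <- order(-manual, seq_len(V))
  expect_identical(pm$variable_ranking$variable_id,
                   fx$t$variable_index[ord])
})

test_that("planted-signal recovery report behaves at the extremes", {
  fx <- att_fixture()
  pm <- population_map(fx$att, fx$t)
  empty <- list(risk_spec = NULL)
  r0 <- planted_signal_report(empty, pm)
  expect_true(is.na(r0$recovery_fraction))
  expect_match(r0$flag, "undefined")
  # uniform attention: a random planted variable lands in the top decile
  # with probability ~ 1/10 (hypergeometric expectation), so the expected
  # recovery of a single planted variable is the decile fraction
  expect_identical(r0$top_decile_size, NA_integer_)
  truth <- list(risk_spec = data.frame(variable_id = fx$t$variable_index[1],
                                       effect_size = 1,
                                       recency_profile = "last_year_only"))
  r1 <- planted_signal_report(truth, pm)
  expect_identical(r1$top_decile_size, as.integer(ceiling(9 / 10)))
  expect_true(r1$recovery_fraction %in% c(0, 1))
  bad <- list(risk_spec = data.frame(variable_id = "ghost",
                                     effect_size = 1,
                                     recency_profile = "uniform"))
  expect_error(planted_signal_report(bad, pm), "missing from")
})

test_that("patient maps keep top-k per year and rescale onto [0, 1]", {
  fx <- att_fixture()
  pid <- fx$t$patient_ids[2]
  m5 <- patient_map(fx$att, fx$t, pid, k = 5L)
  for (tt in unique(m5$cells$period)) {
    shown <- m5$cells[m5$cells$period == tt, ]
    n_unmasked <- sum(fx$t$value_mask[2, tt, ] == 1)
    expect_lte(nrow(shown), 5L)
    expect_identical(nrow(shown), min(5L, n_unmasked))
  }
  expect_true(all(m5$cells$alpha_scaled >= 0 & m5$cells$alpha_scaled <= 1))
  expect_equal(max(m5$cells$alpha_scaled), 1)
  # k = V shows every unmasked variable
  mV <- patient_map(fx$att, fx$t, pid, k = dim(fx$att$alpha)[3])
  for (tt in unique(mV$cells$period)) {
    expect_identical(nrow(mV$cells[mV$cells$period == tt, ]),
                     sum(fx$t$value_mask[2, tt, ] == 1))
  }
})

test_that("min-max rescaling preserves the within-display ranking", {
  fx <- att_fixture(seed = 101)
  for (pid in fx$t$patient_ids[1:6]) {
    pmap <- patient_map(fx$att, fx$t, pid, k = 4L)
    expect_identical(order(pmap$cells$alpha_raw),
                     order(pmap$cells$alpha_scaled))
  }
})

test_that("rendered maps round-trip through CSV", {
  fx <- att_fixture(V = 12)     # enough variables for a full top-10
  pm <- population_map(fx$att, fx$t)
  img <- tempfile(fileext = ".png")
  out <- render_maps(pm, img)
  expect_true(file.exists(out$image))
  csv <- read.csv(out$csv)
  # 10 top-variable columns + slot + the time-attention column
  expect_identical(ncol(csv), 12L)
  expect_identical(names(csv)[ncol(csv)], "time_attention")
  for (j in seq_along(pm$top_variables)) {
    v <- pm$top_variables[j]
    expect_equal(csv[[make.names(v)]],
                 pm$mean_alpha[, match(v, pm$variable_index)])
  }
  expect_equal(csv$time_attention, pm$mean_beta)
  unlink(c(out$image, out$csv))
})

test_that("patient map rendering writes image and matching CSV", {
  fx <- att_fixture()
  pmap <- patient_map(fx$att, fx$t, fx$t$patient_ids[1])
  img <- tempfile(fileext = ".png")
  out <- render_maps(pmap, img)
  csv <- read.csv(out$csv)
  expect_identical(nrow(csv), nrow(pmap$cells))
  expect_equal(csv$alpha_raw, pmap$cells$alpha_raw)
  unlink(c(out$image, out$csv))
})
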