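# score vectors realizing a fixed confusion matrix at threshold 0.5
confusion_scores <- function(tp, fn, fp, tn) {
  list(y = c(rep(1, tp), rep(1, fn), rep(0, fp), rep(0, tn)),
       p = c(rep(0.9, tp), rep(0.1, fn), rep(0.9, fp), rep(0.1, tn)))
}

test_that("kappa, precision and recall match the closed form", {
  cs <- confusion_scores(40, 10, 20, 30)
  m <- compute_metrics(cs$y, cs$p)
  expect_equal(m$precision, 40 / 60)
  expect_equal(m$recall, 0.8)
  # p_o = 0.7, p_e = 0.5 -> kappa = 0.4
  expect_equal(m$cohens_kappa, 0.4)
})

test_that("kappa matches the contingency formula on random confusions", {
  set.seed(17)
  for (r in 1:100) {
    cells <- rmultinom(1, size = sample(40:400, 1), prob = runif(4, 0.05, 1))
    cs <- confusion_scores(cells[1], cells[2], cells[3], cells[4])
    n <- sum(cells)
    po <- (cells[1] + cells[4]) / n
    pe <- ((cells[1] + cells[3]) * (cells[1] + cells[2]) +
             (cells[2] + cells[4]) * (cells[3] + cells[4])) / n^2
    expected <- if (pe == 1) ifelse(po == 1, 1, 0) else (po - pe) / (1 - pe)
    expect_equal(cohens_kappa(cs$y, cs$p), expected, tolerance = 1e-12)
  }
})

test_that("rank-based ROC-AUC equals brute-force pairwise concordance", {
  set.seed(23)
  for (r in 1:25) {
    n <- sample(20:300, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    p <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    expect_equal(roc_auc(y, p), brute_force_auc(y, p), tolerance = 1e-12)
  }
})

test_that("degenerate score patterns hit the known AUC values", {
  y <- c(0, 0, 1, 1)
  expect_equal(roc_auc(y, c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(pr_auc(y, c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(y, rep(0.5, 4)), 0.5)
  expect_true(is.na(roc_auc(c(1, 1), c(0.1, 0.2))))
  expect_match(attr(roc_auc(c(1, 1), c(0.1, 0.2)), "reason"),
               "single-class")
})

test_that("ROC-AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(29)
  y <- rbinom(200, 1, 0.3); p <- runif(200)
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(y, p), ref, tolerance = 1e-12)
})

test_that("bootstrap intervals are seeded, ordered and degenerate-safe", {
  set.seed(31)
  y <- rbinom(300, 1, 0.4); p <- runif(300) * 0.5 + y * 0.3
  a <- bootstrap_ci(y, p, roc_auc, B = 200L, seed = 7L)
  b <- bootstrap_ci(y, p, roc_auc, B = 200L, seed = 7L)
  expect_identical(a, b)
  expect_lte(a$ci_low, a$ci_high)
  # a zero-variance metric collapses the interval onto the point
  const_metric <- function(y, p) 0.42
  d <- bootstrap_ci(y, p, const_metric, B = 50L, seed = 1L)
  expect_identical(c(d$point, d$ci_low, d$ci_high), rep(0.42, 3))
})

test_that("bootstrap intervals shrink roughly like sqrt(n)", {
  set.seed(37)
  gen <- function(n) {
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(1.5 * x))
    list(y = y, p = plogis(1.5 * x))
  }
  small <- gen(200); big <- gen(20000)
  ci_s <- bootstrap_ci(small$y, small$p, roc_auc, B = 200L, seed = 5L)
  ci_b <- bootstrap_ci(big$y, big$p, roc_auc, B = 200L, seed = 5L)
  expect_gt(ci_s$ci_high - ci_s$ci_low, ci_b$ci_high - ci_b$ci_low)
})

test_that("interval contains the point estimate on continuous metrics", {
  set.seed(41)
  hits <- 0L
  for (r in 1:20) {
    n <- 150
    x <- rnorm(n); y <- rbinom(n, 1, plogis(x))
    ci <- bootstrap_ci(y, plogis(x), roc_auc, B = 200L, seed = r)
    hits <- hits + (ci$ci_low <= ci$point && ci$point <= ci$ci_high)
  }
  expect_gte(hits, 19L)
})

test_that("calibration bins partition the sample", {
  set.seed(43)
  y <- rbinom(500, 1, 0.3); p <- runif(500)
  ct <- calibration_table(y, p)
  expect_identical(nrow(ct), 20L)
  expect_equal(ct$hi - ct$lo, rep(0.05, 20))
  expect_identical(sum(ct$n), 500L)
  expect_identical(ct$n_pos + ct$n_neg, ct$n)
})

test_that("all mass in one bin is handled", {
  ct <- calibration_table(rep(0, 50), rep(0.03, 50))
  expect_identical(ct$n[1], 50L)
  expect_equal(ct$observed[1], 0)
  expect_true(all(ct$n[-1] == 0))
})

test_that("boundary probabilities land in the edge bins", {
  ct <- calibration_table(c(0, 1), c(0, 1))
  expect_identical(ct$n[1], 1L)
  expect_identical(ct$n[20], 1L)
})

test_that("stratified reports fan out and tolerate degenerate strata", {
  set.seed(47)
  n <- 240
  strata <- rep(c("F", "M"), each = n / 2)
  x <- rnorm(n)
  # stronger signal planted in stratum F
  slope <- ifelse(strata == "F", 2.5, 0.4)
  y <- rbinom(n, 1, plogis(slope * x))
  p <- plogis(slope * x)
  rep2 <- stratified_report(y, p, strata, B = 100L, seed = 3L)
  expect_identical(sort(names(rep2)), c("F", "M"))
  get_auc <- function(r) r$point[r$metric == "roc_auc"]
  expect_gt(get_auc(rep2$F), get_auc(rep2$M))
  # single-class stratum: AUCs missing, class metrics present
  y2 <- y; y2[strata == "M"] <- 0
  rep3 <- stratified_report(y2, p, strata, B = 50L, seed = 3L)
  expect_true(is.na(rep3$M$point[rep3$M$metric == "roc_auc"]))
  expect_true(is.na(rep3$M$point[rep3$M$metric == "pr_auc"]))
  expect_false(is.na(rep3$M$point[rep3$M$metric == "cohens_kappa"]))
})

test_that("age strata use the default edges", {
  s <- age_strata(c(65, 74.9, 75, 84.9, 85, 99))
  expect_identical(as.character(s),
                   c("65-74", "65-74", "75-84", "75-84", "85+", "85+"))
})
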