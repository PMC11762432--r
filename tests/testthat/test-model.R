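test_that("masked softmax follows the restriction contract", {
  # two-term softmax over the unmasked entries of (1, 2, 3)
  w <- masked_softmax(c(1, 2, 3), c(1, 0, 1))
  expect_equal(w, c(0.1192, 0, 0.8808), tolerance = 1e-4)
  expect_equal(sum(w), 1)
  # singleton
  expect_identical(masked_softmax(c(5, -2, 0), c(0, 1, 0)), c(0, 1, 0))
  # symmetry
  expect_equal(masked_softmax(rep(1.3, 4), c(1, 1, 0, 1)),
               c(1, 1, 0, 1) / 3)
  # all masked: zero vector, flagged
  w0 <- masked_softmax(c(1, 2), c(0, 0))
  expect_identical(as.numeric(w0), c(0, 0))
  expect_true(attr(w0, "all_masked"))
})

test_that("analytic gradients match finite differences (GRU and LSTM)", {
  t <- random_tensor(3, 4, 5, seed = 11)
  y <- c(1, 0, 1)
  for (tp in c("GRU", "LSTM")) {
    pp <- random_params(tp, U = 4L, V = 5L, dense = 1L, seed = 13L)
    type <- if (tp == "GRU") 0L else 1L
    f <- function(p) hanEHR:::cpp_forward(p, t$X, t$value_mask,
                                          t$period_mask, t$S, type, 1L,
                                          FALSE, TRUE, y)
    out <- f(pp$params)
    g <- out$grads
    set.seed(99)
    eps <- 1e-6
    for (nm in names(pp$params)) {
      k <- sample(length(pp$params[[nm]]), 1)
      p1 <- pp$params; p1[[nm]][k] <- p1[[nm]][k] + eps
      p2 <- pp$params; p2[[nm]][k] <- p2[[nm]][k] - eps
      num <- (f(p1)$loss - f(p2)$loss) / (2 * eps)
      expect_equal(as.numeric(g[[nm]])[k], num, tolerance = 1e-4,
                   label = paste(tp, "grad", nm))
    }
  }
})

test_that("probabilities are valid and deterministic under a fixed seed", {
  t <- random_tensor(20, 5, 8, seed = 21)
  for (tp in c("GRU", "LSTM")) {
    pp <- random_params(tp, U = 6L, V = 8L, seed = 31L)
    p1 <- forward_p(pp, t)
    p2 <- forward_p(pp, t)
    expect_true(all(p1 >= 0 & p1 <= 1))
    expect_identical(p1, p2)
  }
})

test_that("attention weights normalize over unmasked slots", {
  t <- random_tensor(30, 6, 10, seed = 41)
  for (tp in c("GRU", "LSTM")) {
    pp <- random_params(tp, U = 5L, V = 10L, seed = 43L)
    fw <- forward_att(pp, t)
    for (i in 1:30) {
      expect_equal(sum(fw$beta[i, ]), 1, tolerance = 1e-12)
      expect_true(all(fw$beta[i, t$period_mask[i, ] == 0] == 0))
      for (tt in which(t$period_mask[i, ] == 1)) {
        expect_equal(sum(fw$alpha[i, tt, ]), 1, tolerance = 1e-12)
        expect_true(all(fw$alpha[i, tt,
                                 t$value_mask[i, tt, ] == 0] == 0))
      }
    }
  }
})

test_that("padded periods give exactly zero context and attention", {
  t <- random_tensor(6, 5, 7, seed = 51)
  pp <- random_params("GRU", U = 4L, V = 7L, seed = 53L)
  enc <- hanEHR:::cpp_encode_period(pp$params, t$X, t$value_mask,
                                    t$period_mask, 0L)
  for (i in 1:6) for (tt in which(t$period_mask[i, ] == 0)) {
    expect_identical(unname(enc$contexts[i, tt, ]), rep(0, 4))
    expect_identical(unname(enc$alpha[i, tt, ]), rep(0, 7))
  }
})

test_that("a real period with all values missing yields zero context", {
  t <- random_tensor(4, 4, 6, seed = 61)
  t$value_mask[2, 3, ] <- 0
  t$X[2, 3, ] <- 0
  pp <- random_params("GRU", U = 4L, V = 6L, seed = 63L)
  enc <- hanEHR:::cpp_encode_period(pp$params, t$X, t$value_mask,
                                    t$period_mask, 0L)
  expect_identical(unname(enc$contexts[2, 3, ]), rep(0, 4))
  expect_identical(unname(enc$alpha[2, 3, ]), rep(0, 6))
})

test_that("a single real period takes all the time attention", {
  t <- random_tensor(5, 6, 4, seed = 71)
  t$period_mask[3, ] <- 0; t$period_mask[3, 6] <- 1
  t$value_mask[3, 1:5, ] <- 0; t$X[3, 1:5, ] <- 0
  pp <- random_params("LSTM", U = 4L, V = 4L, seed = 73L)
  fw <- forward_att(pp, t)
  expect_equal(fw$beta[3, ], c(0, 0, 0, 0, 0, 1), tolerance = 1e-12)
})

test_that("encode_sequence rejects an all-padded patient", {
  t <- random_tensor(3, 4, 5, seed = 81)
  pp <- random_params("GRU", U = 4L, V = 5L, seed = 83L)
  enc <- hanEHR:::cpp_encode_period(pp$params, t$X, t$value_mask,
                                    t$period_mask, 0L)
  model <- structure(list(params = pp$params, config = pp$cfg),
                     class = "han_model")
  bad_mask <- t$period_mask; bad_mask[1, ] <- 0
  expect_error(encode_sequence(model, enc$contexts, bad_mask),
               "all periods padded")
})

test_that("the network learns a noiseless linearly-separable signal", {
  # capacity sanity: one planted variable, deterministic labels
  set.seed(9)
  B <- 400; T_ <- 3; V <- 5
  X <- array(rnorm(B * T_ * V), dim = c(B, T_, V))
  t <- structure(list(
    X = X, value_mask = array(1, dim = dim(X)),
    period_mask = matrix(1, B, T_), S = matrix(0, B, 2),
    variable_index = paste0("v", 1:V),
    static_index = c("sex", "ses_quintile"),
    patient_ids = sprintf("P%04d", 1:B),
    period_years = matrix(2010L, B, T_), T_max = T_
  ), class = "feature_tensor")
  y <- as.integer(X[, T_, 2] > 0)
  labels <- data.frame(patient_id = t$patient_ids, y = y)
  fit <- han_fit(t, labels, "y",
                 model_config("GRU", units = 16L, seed = 2L),
                 toy_schema(t), train_ids = t$patient_ids,
                 epochs = 20L, batch_size = 32L)
  expect_gte(roc_auc(y, predict(fit, t)), 0.99)
})

test_that("training is reproducible under a fixed seed", {
  cd <- fixture_cohort()
  tz <- cd$tz
  ids <- tz$tensor$patient_ids
  fit1 <- han_fit(tz$tensor, tz$labels, "mortality",
                  model_config("GRU", units = 8L, seed = 4L),
                  fixture_schema(), train_ids = ids[1:150],
                  epochs = 1L, batch_size = 64L)
  fit2 <- han_fit(tz$tensor, tz$labels, "mortality",
                  model_config("GRU", units = 8L, seed = 4L),
                  fixture_schema(), train_ids = ids[1:150],
                  epochs = 1L, batch_size = 64L)
  expect_identical(fit1$params, fit2$params)
  expect_identical(predict(fit1, tz$tensor), predict(fit2, tz$tensor))
})
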