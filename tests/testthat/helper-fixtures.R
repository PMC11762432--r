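# Shared in-code fixtures. Heavier objects are memoized so several test
# files can reuse one small synthetic cohort.

.fixture_env <- new.env(parent = emptyenv())

fixture_schema <- function() {
  if (is.null(.fixture_env$schema))
    .fixture_env$schema <- build_default_schema()
  .fixture_env$schema
}

# small synthetic cohort + tensorized pipeline output, shared across files
fixture_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- synthetic_config(n_patients = 300L, seed = 42L)
    cd <- generate_cohort(cfg, fixture_schema())
    tz <- tensorize(cd$events, cd$statics, fixture_schema(),
                    eligibility_config(window = 1L))
    .fixture_env$cohort <- list(cfg = cfg, events = cd$events,
                                statics = cd$statics, truth = cd$truth,
                                tz = tz)
  }
  .fixture_env$cohort
}

# hand-made raw arrays for model-level tests: B patients, values standard
# normal at unmasked positions, ~30% of values missing inside real periods
random_tensor <- function(B, T_, V, seed, p_missing = 0.3,
                          min_real = 1L) {
  set.seed(seed)
  m <- matrix(0, B, T_)
  for (i in seq_len(B)) {
    len <- min_real + sample.int(T_ - min_real + 1L, 1) - 1L
    m[i, (T_ - len + 1):T_] <- 1          # right-aligned histories
  }
  Mv <- array(0, dim = c(B, T_, V))
  for (i in seq_len(B)) for (t in seq_len(T_)) if (m[i, t] == 1)
    Mv[i, t, ] <- rbinom(V, 1, 1 - p_missing)
  X <- array(rnorm(B * T_ * V), dim = c(B, T_, V)) * Mv
  structure(list(
    X = X, value_mask = Mv, period_mask = m,
    S = matrix(rnorm(B * 2), B, 2),
    variable_index = sprintf("v%03d", seq_len(V)),
    static_index = c("sex", "ses_quintile"),
    patient_ids = sprintf("P%04d", seq_len(B)),
    period_years = matrix(rep(seq_len(T_) + 2009L, each = B), B, T_),
    T_max = T_, normalized = TRUE
  ), class = "feature_tensor")
}

# minimal schema matching a random_tensor (all continuous)
toy_schema <- function(tensor) {
  structure(list(
    variables = data.frame(variable_id = tensor$variable_index,
                           family = "toy", value_type = "continuous",
                           agg_kind = "mean", domain = "lab",
                           code = NA_character_, ref_low = NA_real_,
                           ref_high = NA_real_),
    families = data.frame(family = "toy",
                          n_variables = length(tensor$variable_index)),
    static_variables = c("sex", "ses_quintile"),
    total_dynamic = length(tensor$variable_index), total_static = 2L
  ), class = "ehr_schema")
}

random_params <- function(rnn_type, U, V, d = 4L, Vs = 2L, dense = 0L,
                          seed = 1L) {
  cfg <- model_config(rnn_type, units = U, dense = dense, embed_dim = d,
                      seed = seed)
  set.seed(seed)
  list(cfg = cfg, params = hanEHR:::init_params(cfg, V, Vs))
}

forward_p <- function(pp, tensor, dense = 0L) {
  hanEHR:::cpp_forward(pp$params, tensor$X, tensor$value_mask,
                       tensor$period_mask, tensor$S,
                       if (pp$cfg$rnn_type == "GRU") 0L else 1L,
                       dense, FALSE, FALSE)$p
}

forward_att <- function(pp, tensor, dense = 0L) {
  hanEHR:::cpp_forward(pp$params, tensor$X, tensor$value_mask,
                       tensor$period_mask, tensor$S,
                       if (pp$cfg$rnn_type == "GRU") 0L else 1L,
                       dense, TRUE, FALSE)
}

# brute-force pairwise concordance (positive-negative pairs, ties 1/2)
brute_force_auc <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) s <- s + sum(a > neg) + 0.5 * sum(a == neg)
  s / (length(pos) * length(neg))
}
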