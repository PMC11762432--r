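#' Model configuration
#'
#' One point of the hyperparameter grid: recurrent-layer type, units, and
#' presence of a dense layer before the output. The same recurrent type and
#' unit count are used at both attention levels (variable and time).
#'
#' @param rnn_type `"GRU"` or `"LSTM"`.
#' @param units Recurrent units `U` at both levels.
#' @param dense 0 or 1: ReLU dense layer (of `U` units) before the sigmoid
#'   output.
#' @param embed_dim Dimension of the learned per-variable embedding that
#'   lifts each scalar value into the per-period recurrence (default 8).
#' @param seed Seed for parameter initialization and batch shuffling.
#' @return A list of class `model_config`.
#' @export
model_config <- function(rnn_type = c("GRU", "LSTM"), units = 64L,
                         dense = 0L, embed_dim = 8L, seed = 1L) {
  rnn_type <- match.arg(rnn_type)
  if (units <= 0) stop("units must be positive")
  if (!dense %in% c(0L, 1L)) stop("dense must be 0 or 1")
  structure(list(rnn_type = rnn_type, units = as.integer(units),
                 dense = as.integer(dense), embed_dim = as.integer(embed_dim),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Mask-aware softmax
#'
#' Softmax restricted to unmasked entries: masked entries receive weight
#' exactly 0 and the unmasked weights sum to 1. An all-masked input yields
#' an all-zero vector flagged with attribute `all_masked` (the consumer
#' must skip the period).
#'
#' @param scores Numeric vector of raw scores.
#' @param mask Binary vector of the same length (1 = participate).
#' @return Weight vector summing to 1 over unmasked entries.
#' @export
masked_softmax <- function(scores, mask) {
  stopifnot(length(scores) == length(mask))
  w <- numeric(length(scores))
  on <- mask > 0.5
  if (!any(on)) {
    attr(w, "all_masked") <- TRUE
    return(w)
  }
  e <- exp(scores[on] - max(scores[on]))
  w[on] <- e / sum(e)
  w
}

rnn_code <- function(cfg) if (cfg$rnn_type == "GRU") 0L else 1L

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# Parameter initialization; draws come from R's RNG so a single seed makes
# the whole fit reproducible. LSTM forget-gate biases start at 1.
init_params <- function(cfg, V, V_static) {
  U <- cfg$units; d <- cfg$embed_dim; A <- U
  G <- if (cfg$rnn_type == "GRU") 3L else 4L
  # each embedding row is an independent 1 -> d map (fan-in 1), so it is
  # initialized at the per-row Glorot scale, not the V x d matrix scale
  emb_lim <- sqrt(6 / (1 + d))
  p <- list(
    emb_W = matrix(runif(V * d, -emb_lim, emb_lim), V, d),
    emb_b = matrix(0, V, d),
    in_Wx = glorot(d, G * U),
    in_b  = numeric(G * U),
    in_att_W = glorot(U, A),
    in_att_b = numeric(A),
    in_att_v = as.numeric(glorot(A, 1)),
    out_att_W = glorot(2 * U, A),
    out_att_b = numeric(A),
    out_att_v = as.numeric(glorot(A, 1))
  )
  if (cfg$rnn_type == "GRU") {
    p$in_Wh_rz <- glorot(U, 2 * U); p$in_Wh_h <- glorot(U, U)
    p$tf_Wx <- glorot(U, 3 * U); p$tf_Wh_rz <- glorot(U, 2 * U)
    p$tf_Wh_h <- glorot(U, U); p$tf_b <- numeric(3 * U)
    p$tb_Wx <- glorot(U, 3 * U); p$tb_Wh_rz <- glorot(U, 2 * U)
    p$tb_Wh_h <- glorot(U, U); p$tb_b <- numeric(3 * U)
  } else {
    p$in_Wh <- glorot(U, 4 * U)
    p$in_b[(U + 1):(2 * U)] <- 1
    p$tf_Wx <- glorot(U, 4 * U); p$tf_Wh <- glorot(U, 4 * U)
    p$tf_b <- numeric(4 * U); p$tf_b[(U + 1):(2 * U)] <- 1
    p$tb_Wx <- glorot(U, 4 * U); p$tb_Wh <- glorot(U, 4 * U)
    p$tb_b <- numeric(4 * U); p$tb_b[(U + 1):(2 * U)] <- 1
  }
  head_in <- 2 * U + V_static
  if (cfg$dense == 1) {
    p$dense_W <- glorot(head_in, U)
    p$dense_b <- numeric(U)
    p$head_w <- as.numeric(glorot(U, 1))
  } else {
    p$head_w <- as.numeric(glorot(head_in, 1))
  }
  p$head_b <- 0
  p
}

count_params <- function(cfg, V, V_static) {
  p <- init_params(cfg, V, V_static)
  sum(vapply(p, length, integer(1)))
}

slice_tensor <- function(tensor, rows) {
  list(X = tensor$X[rows, , , drop = FALSE],
       Mv = tensor$value_mask[rows, , , drop = FALSE],
       m = tensor$period_mask[rows, , drop = FALSE],
       S = tensor$S[rows, , drop = FALSE])
}

#' Fit the hierarchical attention network
#'
#' Trains the mask-aware two-level attention recurrent network with the
#' Adam optimizer on binary cross-entropy. Normalization statistics are
#' fitted on the training patients only and stored inside the returned
#' model, so `predict()` can be applied to raw tensors without leakage.
#' When validation ids are supplied, training stops early once the
#' validation ROC-AUC has not improved for `patience` epochs and the best
#' parameters are restored.
#'
#' @param tensor A raw (unnormalized) `feature_tensor`.
#' @param labels Label table from [tensorize()] (or any data.frame with
#'   `patient_id` and the outcome column).
#' @param outcome One of `"mortality"`, `"nursing_home"`, `"home_care"`.
#' @param config A [model_config()].
#' @param schema The feature schema used to build the tensor.
#' @param train_ids,val_ids Patient-id memberships; validation is optional.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size (default 64; small batches give the
#'   attention softmax over hundreds of variables enough optimizer steps
#'   to concentrate).
#' @param lr Adam learning rate (default 1e-2).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param verbose Print per-epoch loss / validation AUC.
#' @return An object of class `han_model` (parameters, config,
#'   normalization stats, training history).
#' @export
han_fit <- function(tensor, labels, outcome, config, schema,
                    train_ids, val_ids = NULL,
                    epochs = 8L, batch_size = 64L, lr = 1e-2,
                    patience = 5L, verbose = FALSE) {
  stopifnot(inherits(config, "model_config"))
  labels <- data.table::as.data.table(labels)
  if (!outcome %in% names(labels)) stop("unknown outcome: ", outcome)
  y_all <- labels[[outcome]][match(tensor$patient_ids, labels$patient_id)]

  stats <- fit_normalizer(tensor, train_ids, schema)
  tn <- apply_normalizer(tensor, stats)

  rows_tr <- match(train_ids, tn$patient_ids)
  if (anyNA(rows_tr)) stop("train_ids missing from tensor")
  y_tr <- y_all[rows_tr]
  if (anyNA(y_tr)) stop("training labels missing")

  set.seed(config$seed)
  V <- dim(tn$X)[3]
  params <- init_params(config, V, ncol(tn$S))
  type <- rnn_code(config)

  # Adam state (flattened per parameter)
  mstate <- lapply(params, function(x) numeric(length(x)))
  vstate <- lapply(params, function(x) numeric(length(x)))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L

  val_rows <- if (!is.null(val_ids)) match(val_ids, tn$patient_ids)
  best_auc <- -Inf; best_params <- params; wait <- 0L
  history <- list()

  for (ep in seq_len(epochs)) {
    ord <- sample(length(rows_tr))
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, length(ord), by = batch_size)) {
      bidx <- rows_tr[ord[start:min(start + batch_size - 1, length(ord))]]
      sl <- slice_tensor(tn, bidx)
      fb <- cpp_forward(params, sl$X, sl$Mv, sl$m, sl$S, type,
                        config$dense, FALSE, TRUE, y_all[bidx])
      ep_loss <- ep_loss + fb$loss; nb <- nb + 1L
      step <- step + 1L
      g <- fb$grads
      for (nmp in names(params)) {
        gv <- as.numeric(g[[nmp]])
        mstate[[nmp]] <- b1 * mstate[[nmp]] + (1 - b1) * gv
        vstate[[nmp]] <- b2 * vstate[[nmp]] + (1 - b2) * gv^2
        mhat <- mstate[[nmp]] / (1 - b1^step)
        vhat <- vstate[[nmp]] / (1 - b2^step)
        params[[nmp]][] <- params[[nmp]][] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    rec <- list(epoch = ep, loss = ep_loss / nb)
    if (!is.null(val_ids)) {
      pv <- predict_with_params(params, config, tn, val_rows)
      auc <- roc_auc(y_all[val_rows], pv)
      rec$val_auc <- auc
      if (is.finite(auc) && auc > best_auc + 1e-6) {
        best_auc <- auc; best_params <- params; wait <- 0L
      } else {
        wait <- wait + 1L
      }
      if (verbose)
        message(sprintf("epoch %d  loss %.4f  val AUC %.4f", ep, rec$loss, auc))
      history[[ep]] <- rec
      if (wait >= patience) break
    } else {
      if (verbose) message(sprintf("epoch %d  loss %.4f", ep, rec$loss))
      history[[ep]] <- rec
    }
  }
  if (!is.null(val_ids) && is.finite(best_auc)) params <- best_params

  structure(list(
    params = params, config = config, norm_stats = stats,
    outcome = outcome, variable_index = tn$variable_index,
    history = data.table::rbindlist(history, fill = TRUE),
    epochs_run = length(history),
    train_ids = train_ids, val_ids = val_ids
  ), class = "han_model")
}

predict_with_params <- function(params, config, tensor_n, rows,
                                batch_size = 1024L, attention = FALSE) {
  n <- length(rows)
  p <- numeric(n)
  alpha <- NULL; beta <- NULL
  if (attention) {
    dims <- dim(tensor_n$X)
    alpha <- array(0, dim = c(n, dims[2], dims[3]))
    beta <- matrix(0, n, dims[2])
  }
  for (start in seq(1, n, by = batch_size)) {
    sel <- start:min(start + batch_size - 1, n)
    sl <- slice_tensor(tensor_n, rows[sel])
    fw <- cpp_forward(params, sl$X, sl$Mv, sl$m, sl$S,
                      rnn_code(config), config$dense, attention, FALSE)
    p[sel] <- fw$p
    if (attention) {
      alpha[sel, , ] <- fw$alpha
      beta[sel, ] <- fw$beta
    }
  }
  if (attention) list(p = p, alpha = alpha, beta = beta) else p
}

#' Predict outcome probabilities (and attention maps)
#'
#' Runs the forward pass on a feature tensor. The model's stored
#' normalization statistics are applied unless the tensor is already
#' normalized. With `attention = TRUE` the per-patient attention maps are
#' returned: `alpha[i, t, v]` (variable-level, summing to 1 over unmasked
#' variables of each real period) and `beta[i, t]` (time-level, summing to
#' 1 over real periods).
#'
#' @param object A fitted `han_model`.
#' @param tensor A `feature_tensor`.
#' @param attention Return attention maps alongside probabilities.
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return A named vector of probabilities, or a list `p`, `alpha`, `beta`.
#' @export
predict.han_model <- function(object, tensor, attention = FALSE,
                              batch_size = 1024L, ...) {
  stopifnot(inherits(tensor, "feature_tensor"))
  if (!identical(object$variable_index, tensor$variable_index))
    stop("tensor variables do not match the model")
  tn <- if (isTRUE(tensor$normalized)) tensor else
    apply_normalizer(tensor, object$norm_stats)
  if (any(rowSums(tn$period_mask) == 0))
    stop("patient with no real periods: cannot predict")
  res <- predict_with_params(object$params, object$config, tn,
                             seq_along(tn$patient_ids), batch_size,
                             attention)
  if (attention) {
    names(res$p) <- tn$patient_ids
    res
  } else {
    setNames(res, tn$patient_ids)
  }
}

#' @export
print.han_model <- function(x, ...) {
  cat(sprintf("<han_model> %s(%d units), dense=%d, outcome=%s, %d epochs\n",
              x$config$rnn_type, x$config$units, x$config$dense,
              x$outcome, x$epochs_run))
  invisible(x)
}

#' Variable-level encoding of each period
#'
#' Applies the per-period variable-level recurrence and masked attention of
#' a model to a tensor, returning the period context vectors and the
#' variable-level attention weights. Padded periods yield exactly zero
#' contexts and zero attention; a real period whose variables are all
#' unrecorded yields a zero context with a warning.
#'
#' @param model A `han_model` (or a bare parameter list with `config`).
#' @param tensor A `feature_tensor` (normalized or raw).
#' @return List with `contexts` (`[n, T, U]`) and `alpha` (`[n, T, V]`).
#' @export
encode_period <- function(model, tensor) {
  tn <- if (isTRUE(tensor$normalized)) tensor else
    apply_normalizer(tensor, model$norm_stats)
  res <- cpp_encode_period(model$params, tn$X, tn$value_mask,
                           tn$period_mask, rnn_code(model$config))
  degenerate <- tn$period_mask == 1 &
    apply(tn$value_mask, c(1, 2), sum) == 0
  if (any(degenerate))
    warning(sum(degenerate),
            " real period(s) have no recorded variables; zero context used")
  res
}

#' Time-level encoding of a context sequence
#'
#' Runs the bidirectional recurrence and masked time-level attention over
#' per-period contexts, returning the patient summary vector and the
#' time-attention weights beta.
#'
#' @param model A `han_model`.
#' @param contexts `[n, T, U]` array from [encode_period()].
#' @param period_mask `[n, T]` binary matrix of real periods.
#' @return List with `summary` (`[n, 2U]`) and `beta` (`[n, T]`).
#' @export
encode_sequence <- function(model, contexts, period_mask) {
  if (any(rowSums(period_mask) == 0))
    stop("patient with all periods padded: no history to encode")
  cpp_encode_sequence(model$params, contexts, period_mask,
                      rnn_code(model$config))
}
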