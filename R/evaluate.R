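#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance statistic (rank formula), which
#' equals the trapezoidal area under the ROC curve over all thresholds;
#' tied scores count 1/2.
#'
#' @param y_true Binary vector.
#' @param p_pred Numeric scores.
#' @return ROC-AUC in `[0, 1]`; `NA` with a reason attribute when a single
#'   class is present.
#' @export
roc_auc <- function(y_true, p_pred) {
  stopifnot(length(y_true) == length(p_pred))
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) {
    out <- NA_real_
    attr(out, "reason") <- "single-class y_true: ROC-AUC undefined"
    return(out)
  }
  r <- rank(p_pred, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average precision: the sum over score thresholds of the recall increment
#' times the precision at that threshold (step-wise interpolation, tied
#' scores grouped).
#'
#' @inheritParams roc_auc
#' @return PR-AUC in `[0, 1]`; `NA` when no positives are present.
#' @export
pr_auc <- function(y_true, p_pred) {
  stopifnot(length(y_true) == length(p_pred))
  n1 <- sum(y_true == 1)
  if (n1 == 0 || n1 == length(y_true)) {
    out <- NA_real_
    attr(out, "reason") <- "single-class y_true: PR-AUC undefined"
    return(out)
  }
  ord <- order(p_pred, decreasing = TRUE)
  y <- y_true[ord]; s <- p_pred[ord]
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  tp <- cumsum(y)[grp_end]
  n_seen <- grp_end
  prec <- tp / n_seen
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Cohen's kappa at a classification threshold
#'
#' Chance-corrected agreement between the thresholded prediction and the
#' true class, from the closed-form contingency computation
#' `(p_o - p_e) / (1 - p_e)`.
#'
#' @inheritParams roc_auc
#' @param threshold Scores `>= threshold` predict the positive class.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(y_true, p_pred, threshold = 0.5) {
  yhat <- as.integer(p_pred >= threshold)
  n <- length(y_true)
  po <- mean(yhat == y_true)
  pe <- (sum(yhat == 1) * sum(y_true == 1) +
           sum(yhat == 0) * sum(y_true == 0)) / n^2
  if (pe == 1) return(ifelse(po == 1, 1, 0))
  (po - pe) / (1 - pe)
}

#' Classification and ranking metrics
#'
#' Point estimates of Cohen's kappa, ROC-AUC, PR-AUC, precision and recall
#' (sensitivity) at the given threshold.
#'
#' @inheritParams cohens_kappa
#' @return Named list of metric values; AUCs are `NA` with a reason when
#'   `y_true` has a single class, precision is `NA` when nothing is
#'   predicted positive.
#' @export
compute_metrics <- function(y_true, p_pred, threshold = 0.5) {
  stopifnot(length(y_true) == length(p_pred),
            all(y_true %in% c(0, 1)))
  yhat <- as.integer(p_pred >= threshold)
  tp <- sum(yhat == 1 & y_true == 1)
  fp <- sum(yhat == 1 & y_true == 0)
  fn <- sum(yhat == 0 & y_true == 1)
  list(
    cohens_kappa = cohens_kappa(y_true, p_pred, threshold),
    roc_auc = roc_auc(y_true, p_pred),
    pr_auc = pr_auc(y_true, p_pred),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    threshold = threshold
  )
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Resamples the test set with replacement `B` times (seeded), computes the
#' metric on each resample, and returns the 2.5/97.5 percentile interval
#' around the full-sample point estimate. Resamples on which the metric is
#' undefined (a single class drawn) are redrawn and counted.
#'
#' @inheritParams roc_auc
#' @param metric A function `(y_true, p_pred) -> scalar`.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Resampling seed.
#' @param conf Confidence level (default 0.95).
#' @return List with `point`, `ci_low`, `ci_high`, `B`, `n_redraws`.
#' @export
bootstrap_ci <- function(y_true, p_pred, metric, B = 1000L, seed = 1L,
                         conf = 0.95) {
  stopifnot(B >= 1)
  point <- metric(y_true, p_pred)
  if (is.na(point)) stop("metric undefined on the full sample")
  set.seed(seed)
  n <- length(y_true)
  stat <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      v <- metric(y_true[idx], p_pred[idx])
      if (!is.na(v)) break
      redraws <- redraws + 1L
      if (redraws > 100 * B) stop("metric undefined on almost all resamples")
    }
    stat[b] <- v
  }
  a <- (1 - conf) / 2
  ci <- unname(quantile(stat, c(a, 1 - a), type = 7))
  list(point = as.numeric(point), ci_low = ci[1], ci_high = ci[2],
       B = B, n_redraws = redraws)
}

#' Full metrics report with bootstrap intervals
#'
#' The evaluation summary used for every model in the package: point
#' estimate and 95% percentile bootstrap interval (1000 resamples, shared
#' resampling seed across metrics) for Cohen's kappa, ROC-AUC, PR-AUC,
#' precision and recall at the stated threshold.
#'
#' @inheritParams cohens_kappa
#' @param B Bootstrap resamples (default 1000).
#' @param seed Resampling seed.
#' @return A `data.table` of class `metrics_report` with columns `metric`,
#'   `point`, `ci_low`, `ci_high`, plus attributes `threshold`, `B`,
#'   `n_test`.
#' @export
metrics_report <- function(y_true, p_pred, threshold = 0.5, B = 1000L,
                           seed = 1L) {
  metrics <- list(
    cohens_kappa = function(y, p) cohens_kappa(y, p, threshold),
    roc_auc = roc_auc,
    pr_auc = pr_auc,
    precision = function(y, p) compute_metrics(y, p, threshold)$precision,
    recall = function(y, p) compute_metrics(y, p, threshold)$recall
  )
  rows <- lapply(names(metrics), function(mn) {
    f <- metrics[[mn]]
    pt <- f(y_true, p_pred)
    if (is.na(pt)) {
      data.table::data.table(metric = mn, point = NA_real_,
                             ci_low = NA_real_, ci_high = NA_real_,
                             note = attr(pt, "reason") %||% "undefined")
    } else {
      ci <- bootstrap_ci(y_true, p_pred, f, B = B, seed = seed)
      data.table::data.table(metric = mn, point = ci$point,
                             ci_low = ci$ci_low, ci_high = ci$ci_high,
                             note = "")
    }
  })
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "threshold", threshold)
  data.table::setattr(out, "B", B)
  data.table::setattr(out, "n_test", length(y_true))
  data.table::setattr(out, "class", c("metrics_report", class(out)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibration table with 20 probability bins
#'
#' Assigns each patient to one of 20 right-closed predicted-probability
#' bins of width 0.05 (`p = 0` falls in the first bin, `p = 1` in the
#' last) and reports per-bin size, positive/negative counts and observed
#' outcome proportion — the construction behind a calibration plot with the
#' per-class probability bars.
#'
#' @inheritParams roc_auc
#' @return A `data.table` of class `calibration_table`: `bin`, `lo`, `hi`,
#'   `mid`, `n`, `n_pos`, `n_neg`, `observed`.
#' @export
calibration_table <- function(y_true, p_pred) {
  stopifnot(all(p_pred >= 0 & p_pred <= 1))
  breaks <- seq(0, 1, by = 0.05)
  bin <- cut(p_pred, breaks = breaks, include.lowest = TRUE, right = TRUE,
             labels = FALSE)
  out <- data.table::data.table(
    bin = seq_len(20),
    lo = breaks[1:20], hi = breaks[2:21], mid = (breaks[1:20] + breaks[2:21]) / 2
  )
  cnt <- data.table::data.table(bin = bin, y = y_true)[
    , .(n = .N, n_pos = sum(y == 1), n_neg = sum(y == 0)), by = bin]
  out <- merge(out, cnt, by = "bin", all.x = TRUE)
  for (cc in c("n", "n_pos", "n_neg"))
    data.table::set(out, which(is.na(out[[cc]])), cc, 0L)
  out[, observed := ifelse(n > 0, n_pos / n, NA_real_)]
  data.table::setattr(out, "class", c("calibration_table", class(out)))
  out
}

#' Calibration plot
#'
#' Renders the calibration curve (observed outcome proportion per predicted
#' probability bin) together with bars of the per-class probability
#' distributions.
#'
#' @param ct A [calibration_table()].
#' @param path Optional output path (`.png` / `.svg`); when `NULL` the
#'   ggplot object is returned.
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_calibration <- function(ct, path = NULL) {
  dt <- data.table::as.data.table(ct)
  long <- data.table::melt(dt[, .(mid, n_pos, n_neg)], id.vars = "mid",
                           variable.name = "class", value.name = "count")
  long[, frac := count / sum(count), by = class]
  g <- ggplot2::ggplot() +
    ggplot2::geom_col(data = long,
                      ggplot2::aes(x = mid, y = frac, fill = class),
                      position = "dodge", alpha = 0.45, width = 0.04) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_line(data = dt[!is.na(observed)],
                       ggplot2::aes(x = mid, y = observed),
                       colour = "#00796b", linewidth = 1) +
    ggplot2::geom_point(data = dt[!is.na(observed)],
                        ggplot2::aes(x = mid, y = observed),
                        colour = "#00796b") +
    ggplot2::scale_fill_manual(values = c(n_neg = "#1f77b4",
                                          n_pos = "#ff7f0e"),
                               labels = c("negative", "positive")) +
    ggplot2::labs(x = "predicted probability", y = "observed proportion",
                  fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, g, width = 6, height = 4, dpi = 150)
    return(invisible(g))
  }
  g
}

#' Stratified performance report
#'
#' Computes a full [metrics_report()] within each stratum (e.g. sex, or
#' age group at cohort entry). Strata below `min_n` patients are flagged;
#' empty strata are omitted with a log entry.
#'
#' @inheritParams metrics_report
#' @param strata Factor/character vector of stratum labels per patient.
#' @param min_n Minimum stratum size before flagging (default 30).
#' @return Named list of `metrics_report`s with attributes `flagged` and
#'   `omitted`.
#' @export
stratified_report <- function(y_true, p_pred, strata, threshold = 0.5,
                              B = 1000L, seed = 1L, min_n = 30L) {
  stopifnot(length(strata) == length(y_true))
  levs <- unique(as.character(strata))
  out <- list(); flagged <- character(0); omitted <- character(0)
  for (s in levs) {
    sel <- which(as.character(strata) == s)
    if (length(sel) == 0) { omitted <- c(omitted, s); next }
    out[[s]] <- metrics_report(y_true[sel], p_pred[sel],
                               threshold = threshold, B = B, seed = seed)
    if (length(sel) < min_n) flagged <- c(flagged, s)
  }
  attr(out, "flagged") <- flagged
  attr(out, "omitted") <- omitted
  out
}

#' Default age strata at cohort entry
#'
#' @param age_at_entry Numeric ages.
#' @param edges Bin edges (default 65-74, 75-84, 85+).
#' @return Character vector of stratum labels.
#' @export
age_strata <- function(age_at_entry, edges = c(65, 75, 85)) {
  cut(age_at_entry, breaks = c(edges, Inf), right = FALSE,
      labels = c(sprintf("%d-%d", edges[-length(edges)],
                         edges[-1] - 1), sprintf("%d+", edges[length(edges)])))
}
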