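#' Population-level attention map
#'
#' Averages the per-patient attention maps of a (test) cohort: per-slot
#' means of the variable-level weights alpha and of the time-level weights
#' beta, computed only over patients contributing real data at the slot.
#' Histories are right-aligned, so slot `T_max` is the year closest to the
#' prediction for every patient. Variables are ranked by their overall
#' mean contribution — the mean of alpha over all real periods — with ties
#' broken by schema order; optionally the ranking weights each period's
#' alpha by the patient's beta.
#'
#' Raw (unrescaled) weights are reported throughout: variable-level
#' attention is spread over many variables and is therefore substantially
#' smaller than time-level attention; any rescaling is display-only.
#'
#' @param attention List with `alpha` `[n, T, V]` and `beta` `[n, T]` from
#'   `predict(..., attention = TRUE)`.
#' @param tensor The `feature_tensor` the attention was computed on (for
#'   the masks and variable index).
#' @param top_k Number of top variables to extract (default 10).
#' @param weight_by_beta Rank by the beta-weighted mean of alpha instead of
#'   the plain mean.
#' @return An object of class `population_map`: `mean_alpha` `[T, V]`,
#'   `mean_beta` `[T]`, `variable_ranking` (data.table), `top_variables`,
#'   `tie_flag`.
#' @export
population_map <- function(attention, tensor, top_k = 10L,
                           weight_by_beta = FALSE) {
  alpha <- attention$alpha; beta <- attention$beta
  if (is.null(alpha) || is.null(beta)) stop("attention maps missing")
  n <- dim(alpha)[1]
  if (n < 1) stop("population map needs at least one patient")
  Tm <- dim(alpha)[2]; V <- dim(alpha)[3]
  m <- tensor$period_mask
  stopifnot(nrow(m) == n, ncol(m) == Tm)

  contrib <- colSums(m)                      # patients with a real period t
  mean_alpha <- matrix(NA_real_, Tm, V)
  for (t in seq_len(Tm)) {
    if (contrib[t] == 0) next
    sel <- m[, t] == 1
    mean_alpha[t, ] <- colMeans(alpha[sel, t, , drop = FALSE])
  }
  mean_beta <- vapply(seq_len(Tm), function(t)
    if (contrib[t] > 0) mean(beta[m[, t] == 1, t]) else NA_real_,
    numeric(1))

  w <- if (weight_by_beta) beta * m else m
  tot_w <- sum(w)
  overall <- vapply(seq_len(V), function(v) sum(alpha[, , v] * w) / tot_w,
                    numeric(1))
  ord <- order(-overall, seq_len(V))
  ranking <- data.table::data.table(
    variable_id = tensor$variable_index[ord],
    mean_alpha = overall[ord],
    rank = seq_len(V)
  )
  k <- min(top_k, V)
  ties <- length(unique(round(overall, 12))) < V
  structure(list(
    mean_alpha = mean_alpha, mean_beta = mean_beta,
    variable_index = tensor$variable_index,
    variable_ranking = ranking,
    top_variables = ranking$variable_id[seq_len(k)],
    n_patients = n, tie_flag = ties,
    weight_by_beta = weight_by_beta
  ), class = "population_map")
}

#' @export
print.population_map <- function(x, ...) {
  cat(sprintf("<population_map> %d patients; top variables:\n", x$n_patients))
  print(head(x$variable_ranking, length(x$top_variables)))
  invisible(x)
}

#' Patient-level attention map
#'
#' For each real period of one patient, the top-k variables by raw
#' variable-level attention ("which need not be the same every year"),
#' with a display rescaling of the shown weights to `[0, 1]` by min-max
#' over the displayed set only; the raw weights and the time-level beta
#' are reported alongside.
#'
#' @param attention Attention list from `predict(..., attention = TRUE)`.
#' @param tensor The `feature_tensor`.
#' @param patient_id Which patient to map.
#' @param k Variables shown per year (default 5); periods with fewer
#'   unmasked variables show all of them.
#' @return An object of class `patient_map`: `cells` (data.table: period,
#'   year, variable_id, alpha_raw, alpha_scaled), `beta` (data.table:
#'   period, year, beta).
#' @export
patient_map <- function(attention, tensor, patient_id, k = 5L) {
  i <- match(patient_id, tensor$patient_ids)
  if (is.na(i)) stop("unknown patient_id")
  m <- tensor$period_mask[i, ]
  if (!any(m == 1)) stop("patient has no real periods")
  Tm <- length(m)
  cells <- list()
  for (t in which(m == 1)) {
    a <- attention$alpha[i, t, ]
    on <- which(tensor$value_mask[i, t, ] == 1)
    if (!length(on)) next
    top <- on[order(-a[on])][seq_len(min(k, length(on)))]
    cells[[length(cells) + 1L]] <- data.table::data.table(
      period = t, year = tensor$period_years[i, t],
      variable_id = tensor$variable_index[top],
      alpha_raw = a[top]
    )
  }
  cells <- data.table::rbindlist(cells)
  if (nrow(cells)) {
    rng <- range(cells$alpha_raw)
    cells[, alpha_scaled := if (diff(rng) > 0)
      (alpha_raw - rng[1]) / diff(rng) else as.numeric(alpha_raw > 0)]
  }
  beta_dt <- data.table::data.table(
    period = which(m == 1),
    year = tensor$period_years[i, m == 1],
    beta = attention$beta[i, m == 1]
  )
  structure(list(cells = cells, beta = beta_dt, patient_id = patient_id,
                 k = k), class = "patient_map")
}

#' Render an attention map as heatmap + CSV
#'
#' Population maps render as a heatmap with the top variables in the first
#' columns and the time-level attention as the final column (one row per
#' history slot, most recent last); patient maps render the per-year top-k
#' cells. The plotted values are also written as CSV so the figure is
#' exactly reproducible; padded slots are blank, not zero-coloured.
#'
#' @param map A `population_map` or `patient_map`.
#' @param out_path Output image path (`.png`); the CSV lands next to it.
#' @return Invisibly, a list with `image` and `csv` paths.
#' @export
render_maps <- function(map, out_path) {
  csv_path <- sub("\\.[a-zA-Z]+$", ".csv", out_path)
  if (inherits(map, "population_map")) {
    topv <- map$top_variables
    # columns: top variables then the time-attention column
    Tm <- length(map$mean_beta)
    dt <- data.table::data.table(slot = seq_len(Tm))
    for (v in topv)
      dt[[v]] <- map$mean_alpha[, match(v, map$variable_index)]
    dt[["time_attention"]] <- map$mean_beta
    write.csv(dt, csv_path, row.names = FALSE)
    long <- data.table::melt(dt, id.vars = "slot", variable.name = "variable",
                             value.name = "weight")
    long[, variable := factor(variable, levels = c(topv, "time_attention"))]
    g <- ggplot2::ggplot(long[!is.na(weight)],
                         ggplot2::aes(x = variable, y = slot,
                                      fill = weight)) +
      ggplot2::geom_tile() +
      ggplot2::scale_y_reverse() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = NULL, y = "history slot (most recent last)",
                    fill = "attention") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                         hjust = 1))
  } else if (inherits(map, "patient_map")) {
    dt <- map$cells
    write.csv(dt, csv_path, row.names = FALSE)
    g <- ggplot2::ggplot(dt, ggplot2::aes(x = variable_id,
                                          y = factor(year),
                                          fill = alpha_scaled)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
      ggplot2::labs(x = NULL, y = "year", fill = "scaled\nattention",
                    title = paste("patient", map$patient_id)) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                         hjust = 1))
  } else stop("unknown map type")
  ggplot2::ggsave(out_path, g, width = 7, height = 4.5, dpi = 150)
  invisible(list(image = out_path, csv = csv_path))
}
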