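#' Mean logit update by (interval, last)
#'
#' Averages the decoder's logit-Bayesian update `u_Bayes` within each
#' `(interval, last)` group of the evaluation dataset. Diagonal entries
#' (`last == interval`) correspond to actual pulse minutes; positive values
#' there mean the decoder raises the pulse probability above the prior,
#' while negative off-diagonal values mean it confidently rules pulses out.
#' Entries near zero carry no information beyond the prior.
#'
#' @param model A trained [train_pulse_classifier()] decoder.
#' @param datapoints The evaluation datapoints.
#' @return A tibble with `interval`, `last`, `mean_u`, `n`.
#' @export
mean_logit_update <- function(model, datapoints) {
  datapoints |>
    dplyr::mutate(u_bayes = predict_u_bayes(model, datapoints)) |>
    dplyr::group_by(.data$interval, .data$last) |>
    dplyr::summarise(mean_u = mean(.data$u_bayes), n = dplyr::n(),
                     .groups = "drop")
}

#' @rdname mean_logit_update
#' @param update_table A table from `mean_logit_update()`.
#' @return `diagonal_update_curve()`: the diagonal entries
#'   (`interval == last`) as a tibble with `interval`, `mean_u`, `n` --
#'   the decoder's pulse-detection certainty as a function of the
#'   preceding interval.
#' @export
diagonal_update_curve <- function(update_table) {
  update_table |>
    dplyr::filter(.data$last == .data$interval) |>
    dplyr::select("interval", "mean_u", "n") |>
    dplyr::arrange(.data$interval)
}

#' Effective refractory time from a detection-certainty curve
#'
#' The asymptotic certainty is the mean of the curve over its plateau (the
#' top quartile of tested intervals). The effective refractory time is the
#' interval at which the curve first crosses half of that asymptote
#' (linear interpolation between tested intervals) -- the interval at which
#' a second pulse is detected with roughly 50% of full certainty. If the
#' curve already exceeds the half-asymptote at the smallest tested
#' interval, the refractory time is below the tested range.
#'
#' @param curve A tibble with `interval` and `mean_u` (e.g. from
#'   [diagonal_update_curve()]), over at least 3 intervals.
#' @return A one-row tibble with `refractory_min` (minutes, `NA` when not
#'   defined), `asymptote`, `half_level` and `status` (`"ok"`,
#'   `"below support"`, or `"undefined"`).
#' @export
effective_refractory_time <- function(curve) {
  stopifnot(nrow(curve) >= 3)
  curve <- dplyr::arrange(curve, .data$interval)
  q3 <- stats::quantile(curve$interval, 0.75, names = FALSE)
  asym <- mean(curve$mean_u[curve$interval >= q3])
  if (!is.finite(asym) || asym <= 0) {
    return(tibble::tibble(refractory_min = NA_real_, asymptote = asym,
                          half_level = NA_real_, status = "undefined"))
  }
  half <- asym / 2
  if (curve$mean_u[1] >= half) {
    return(tibble::tibble(refractory_min = NA_real_, asymptote = asym,
                          half_level = half, status = "below support"))
  }
  above <- which(curve$mean_u >= half)
  if (length(above) == 0) {
    return(tibble::tibble(refractory_min = NA_real_, asymptote = asym,
                          half_level = half, status = "undefined"))
  }
  i <- min(above)
  x0 <- curve$interval[i - 1]; x1 <- curve$interval[i]
  y0 <- curve$mean_u[i - 1]; y1 <- curve$mean_u[i]
  tibble::tibble(
    refractory_min = x0 + (half - y0) / (y1 - y0) * (x1 - x0),
    asymptote = asym, half_level = half, status = "ok")
}

#' Probability that the kth nearest neighbor transmits
#'
#' For each anchor group (transmitting / non-transmitting) and each
#' k <= `k_max`, the fraction of anchor cells whose kth nearest neighbor
#' (Euclidean distance, excluding self, ties broken by cell order) is
#' transmitting. Elevated curves for transmitting anchors at small k
#' indicate spatial clustering of the transmitting phenotype.
#'
#' @param cells A tibble with `pos_x`, `pos_y` and logical `transmitting`
#'   (one row per cell); needs at least `k_max + 1` cells.
#' @param k_max Largest neighbor rank considered.
#' @return A tibble with `anchor` (`"transmitting"`/`"non-transmitting"`),
#'   `k`, `prob` and `n_anchors`.
#' @export
neighbor_transmission_probability <- function(cells, k_max = 6) {
  n <- nrow(cells)
  stopifnot(n >= k_max + 1, all(c("pos_x", "pos_y", "transmitting") %in%
                                  names(cells)))
  d <- as.matrix(stats::dist(cbind(cells$pos_x, cells$pos_y)))
  diag(d) <- Inf
  nb_flags <- t(vapply(seq_len(n), function(i) {
    ord <- order(d[i, ], seq_len(n))     # ties broken by cell order
    cells$transmitting[ord[seq_len(k_max)]]
  }, logical(k_max)))
  if (k_max == 1) nb_flags <- matrix(nb_flags, ncol = 1)
  purrr::map_dfr(c(TRUE, FALSE), function(anchor_flag) {
    sel <- cells$transmitting == anchor_flag
    tibble::tibble(
      anchor = if (anchor_flag) "transmitting" else "non-transmitting",
      k = seq_len(k_max),
      prob = colMeans(nb_flags[sel, , drop = FALSE]),
      n_anchors = sum(sel))
  })
}

#' Condition-level summary across replicates
#'
#' Aggregates per-replicate summaries (population bitrate, transmitting
#' fraction, transmitting-subpopulation bitrate, mean response amplitude)
#' into per-condition means with standard errors of the mean. A condition
#' with a single replicate reports `NA` SEMs.
#'
#' @param replicate_summaries A tibble with one row per replicate:
#'   `condition`, `replicate_id`, and one or more numeric summary columns.
#' @return A tibble with one row per condition and `<col>_mean`,
#'   `<col>_sem` for every numeric summary column.
#' @export
condition_summary <- function(replicate_summaries) {
  stopifnot("condition" %in% names(replicate_summaries))
  num_cols <- setdiff(
    names(replicate_summaries)[vapply(replicate_summaries, is.numeric,
                                      logical(1))],
    c("condition"))
  replicate_summaries |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      dplyr::across(dplyr::all_of(num_cols),
                    list(mean = ~ mean(.x, na.rm = TRUE),
                         sem = ~ if (dplyr::n() > 1) {
                           stats::sd(.x, na.rm = TRUE) / sqrt(dplyr::n())
                         } else NA_real_)),
      .groups = "drop")
}
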