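#' Pointwise surprisal reduction
#'
#' The information (in bits) gained about the pulse indicator at one
#' minute: `log2 p_posterior(x) - log2 p_prior(x)` evaluated at the
#' realized `x`. Zero when the posterior equals the prior; negative when
#' the decoder's prediction is worse than the prior.
#'
#' @param x Pulse indicators (0/1).
#' @param prior,posterior Probabilities of `x = 1`, strictly inside (0, 1).
#' @return Numeric vector of bits.
#' @export
pointwise_information <- function(x, prior, posterior) {
  stopifnot(length(prior) == length(x) || length(prior) == 1,
            length(posterior) == length(x) || length(posterior) == 1)
  log2(ifelse(x == 1, posterior, 1 - posterior)) -
    log2(ifelse(x == 1, prior, 1 - prior))
}

# attach u, prior, posterior and pointwise information columns
evaluate_datapoints <- function(datapoints, model, protocol) {
  protocol <- as_stimulation_protocol(protocol)
  u <- predict_u_bayes(model, datapoints)
  prior <- protocol_prior(protocol, datapoints$last)
  posterior <- posterior_probability(u, prior)
  datapoints |>
    dplyr::mutate(u_bayes = u, prior = prior, posterior = posterior,
                  info_bits = pointwise_information(.data$x, prior, posterior))
}

#' Split cells into transmitting and non-transmitting subpopulations
#'
#' Sorts cells by their single-cell bitrate and declares non-transmitting
#' the longest prefix whose track-length-weighted mean bitrate is strictly
#' negative; the complement is the transmitting subpopulation. The
#' threshold is the smallest bitrate among transmitting cells, and the
#' transmitting fraction is the weighted share of transmitting cells.
#'
#' @param b Single-cell bitrates (bit/h).
#' @param w Track-length weights (usable minutes per cell).
#' @return A list with `threshold` (bit/h; `Inf` if no cell transmits,
#'   `-Inf` if all do), `transmitting` (logical, original order) and
#'   `fraction` (weighted transmitting share).
#' @export
transmitting_split <- function(b, w = rep(1, length(b))) {
  stopifnot(length(b) >= 1, length(w) == length(b))
  ord <- order(b)
  cm <- cumsum(b[ord] * w[ord]) / cumsum(w[ord])
  neg <- which(cm < 0)
  n_non <- if (length(neg) == 0) 0L else max(neg)
  transmitting <- rep(TRUE, length(b))
  if (n_non > 0) transmitting[ord[seq_len(n_non)]] <- FALSE
  threshold <- if (n_non == length(b)) Inf else if (n_non == 0) -Inf else
    b[ord[n_non + 1L]]
  list(threshold = threshold, transmitting = transmitting,
       fraction = sum(w[transmitting]) / sum(w))
}

#' Estimate single-cell and population bitrates
#'
#' Evaluates the decoder once on every usable data point (no resampling)
#' and aggregates the pointwise surprisal reductions: the bitrate of cell j
#' is the mean over its timepoints times 60 (bit/h, possibly negative), the
#' population bitrate is the track-length-weighted mean of the single-cell
#' bitrates (identically the pooled average over all data points), and the
#' transmitting split is computed either pooled across replicates or per
#' replicate.
#'
#' @param datapoints A datapoint tibble.
#' @param model A trained [train_pulse_classifier()] decoder.
#' @param protocol The assumed [stimulation_protocol()].
#' @param threshold_mode `"pooled"` (one split across replicates, as used
#'   for histograms) or `"per_replicate"` (a split per replicate, as used
#'   for fraction and subpopulation summaries).
#' @return A `bitrate_report` object; see [tidy.bitrate_report()] and
#'   [glance.bitrate_report()].
#' @export
estimate_bitrate <- function(datapoints, model, protocol,
                             threshold_mode = c("pooled", "per_replicate")) {
  threshold_mode <- match.arg(threshold_mode)
  protocol <- as_stimulation_protocol(protocol)
  ev <- evaluate_datapoints(datapoints, model, protocol)
  cells <- ev |>
    dplyr::group_by(.data$replicate_id, .data$cell_id) |>
    dplyr::summarise(b = 60 * mean(.data$info_bits), w = dplyr::n(),
                     .groups = "drop")
  if (threshold_mode == "pooled") {
    sp <- transmitting_split(cells$b, cells$w)
    cells$transmitting <- sp$transmitting
    thresholds <- tibble::tibble(replicate_id = "(pooled)",
                                 threshold = sp$threshold,
                                 fraction = sp$fraction)
  } else {
    cells <- cells |>
      dplyr::group_by(.data$replicate_id) |>
      dplyr::mutate(transmitting = transmitting_split(.data$b, .data$w)$transmitting) |>
      dplyr::ungroup()
    thresholds <- cells |>
      dplyr::group_by(.data$replicate_id) |>
      dplyr::summarise(
        threshold = transmitting_split(.data$b, .data$w)$threshold,
        fraction = transmitting_split(.data$b, .data$w)$fraction,
        .groups = "drop")
  }
  structure(
    list(cells = cells, thresholds = thresholds,
         threshold_mode = threshold_mode,
         entropy_rate = entropy_rate(protocol$dist)),
    class = "bitrate_report")
}

#' @export
print.bitrate_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<bitrate_report> %d cells | population %.2f bit/h (SE %.2f) | transmitting %.0f%% | transmitting-subpop %.2f bit/h | input %.2f bit/h\n",
    g$n_cells, g$bitrate, g$se, 100 * g$fraction_transmitting,
    g$bitrate_transmitting, g$entropy_rate))
  invisible(x)
}

#' Tidy and summarize a bitrate report
#'
#' `tidy()` returns the per-cell table (`cell_id`, `b` in bit/h, weight
#' `w`, transmitting flag); `glance()` returns a one-row population
#' summary: the weighted-mean bitrate, its standard error over cells, the
#' total weight `D`, the transmitting fraction and subpopulation bitrate,
#' and the input entropy rate.
#'
#' @param x A `bitrate_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bitrate_report <- function(x, ...) x$cells

#' @rdname tidy.bitrate_report
#' @export
glance.bitrate_report <- function(x, ...) {
  cells <- x$cells
  D <- sum(cells$w)
  b <- sum(cells$w * cells$b) / D
  se <- sqrt(sum(cells$w^2 * (cells$b - b)^2)) / D
  bt <- if (any(cells$transmitting)) {
    with(cells[cells$transmitting, ], sum(w * b) / sum(w))
  } else NA_real_
  tibble::tibble(
    n_cells = nrow(cells), bitrate = b, se = se, D = D,
    fraction_transmitting = sum(cells$w[cells$transmitting]) / D,
    bitrate_transmitting = bt,
    entropy_rate = x$entropy_rate)
}

#' Channel-specific (dip-only / peak-only) bitrates
#'
#' Runs the full decode-and-estimate pipeline with a restricted trajectory
#' slice: `dip_only` sees minutes `k..k+2` (the calcineurin-mediated dip),
#' `peak_only` sees minutes `k+6..k+12` (the ERK-mediated peak). Training a
#' separate decoder per slice quantifies how much information each pathway
#' carries on its own.
#'
#' @param tracks A standardized track table.
#' @param seq The [pulse_sequence()].
#' @param protocol The assumed [stimulation_protocol()].
#' @param slice_mode `"dip_only"` or `"peak_only"`.
#' @param ... Passed to [train_pulse_classifier()].
#' @return A `bitrate_report`.
#' @export
channel_bitrate <- function(tracks, seq, protocol,
                            slice_mode = c("dip_only", "peak_only"), ...) {
  slice_mode <- match.arg(slice_mode)
  dp <- extract_datapoints(tracks, seq, slice_mode = slice_mode)
  model <- train_pulse_classifier(dp, protocol, ...)
  estimate_bitrate(dp, model, protocol)
}

#' Quadrant table of dip-only vs peak-only transmission
#'
#' Cross-tabulates each cell's transmitting status under the dip-only and
#' peak-only decoders; the four fractions sum to one.
#'
#' @param report_dip,report_peak `bitrate_report`s from [channel_bitrate()].
#' @return A tibble with `dip_transmitting`, `peak_transmitting`, `n`,
#'   `fraction`.
#' @export
quadrant_table <- function(report_dip, report_peak) {
  joined <- dplyr::inner_join(
    dplyr::select(tidy(report_dip), "replicate_id", "cell_id",
                  dip_transmitting = "transmitting"),
    dplyr::select(tidy(report_peak), "replicate_id", "cell_id",
                  peak_transmitting = "transmitting"),
    by = c("replicate_id", "cell_id"))
  joined |>
    dplyr::count(.data$dip_transmitting, .data$peak_transmitting, name = "n") |>
    tidyr::complete(dip_transmitting = c(FALSE, TRUE),
                    peak_transmitting = c(FALSE, TRUE),
                    fill = list(n = 0L)) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
}

#' Write a bitrate report to disk
#'
#' The per-cell table is written as CSV and the population summary as JSON.
#'
#' @param report A `bitrate_report`.
#' @param csv_path,json_path Output paths.
#' @return Invisibly, the report.
#' @export
write_bitrate_report <- function(report, csv_path, json_path) {
  readr::write_csv(tidy(report), csv_path)
  jsonlite::write_json(as.list(glance(report)), json_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
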