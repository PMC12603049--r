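#' Standardize raw KTR tracks
#'
#' Converts raw intensities into the normalized KTR trajectory
#' `y = -log((nuclear - background) / (frame - background))`: background
#' subtraction followed by per-frame normalization (which removes global
#' fluorescence changes caused by the stimulation light and illumination
#' differences across frames and replicates). Minutes at which either
#' background-subtracted intensity is non-positive are flagged missing
#' (`y = NA`).
#'
#' @param raw A raw track table (see [simulate_population()] for columns);
#'   must contain `replicate_id`, `cell_id`, `minute`, `nuclear_mean`,
#'   `frame_mean`.
#' @param background A single background intensity, or a data frame with
#'   columns `replicate_id`, `background` for per-replicate values.
#' @return The input tibble with an added `y` column, ordered by cell and
#'   minute.
#' @export
standardize_tracks <- function(raw, background = 0) {
  stopifnot(all(c("replicate_id", "cell_id", "minute", "nuclear_mean",
                  "frame_mean") %in% names(raw)))
  if (is.data.frame(background)) {
    raw <- dplyr::left_join(raw, background, by = "replicate_id")
  } else {
    raw$background <- background
  }
  raw |>
    dplyr::mutate(
      .nuc = .data$nuclear_mean - .data$background,
      .frm = .data$frame_mean - .data$background,
      y = -log(dplyr::if_else(.data$.nuc > 0 & .data$.frm > 0,
                              .data$.nuc / .data$.frm, NA_real_))) |>
    dplyr::select(-".nuc", -".frm", -"background") |>
    dplyr::arrange(.data$replicate_id, .data$cell_id, .data$minute) |>
    tibble::as_tibble()
}

#' Remove short tracks
#'
#' Drops cells tracked for fewer than `min_length` minutes (inclusive
#' boundary: a track of exactly `min_length` minutes is kept). The default,
#' 180 min, removes tracks shorter than 3 h.
#'
#' @param tracks A standardized track table (one row per cell-minute).
#' @param min_length Minimal track length in minutes.
#' @return The filtered track table.
#' @export
filter_short_tracks <- function(tracks, min_length = 180) {
  tracks |>
    dplyr::group_by(.data$replicate_id, .data$cell_id) |>
    dplyr::filter(dplyr::n() >= min_length) |>
    dplyr::ungroup()
}

#' Preselect receptor-expressing cells
#'
#' Cells with very low or very high receptor expression transmit poorly and
#' are discarded. Per replicate, the track-length-weighted mean `mu` and
#' standard deviation `sigma` (population convention, denominator = total
#' weight) of the per-cell receptor summary -- the mean receptor intensity
#' at pulse minutes -- are computed, and cells are kept inside
#' `[mu, mu + 3 sigma]` for BEAS2B-like lines or
#' `[mu - 0.5 sigma, mu + 2 sigma]` for STE1-like lines.
#'
#' @param tracks A standardized track table with `receptor_mean` and
#'   `cell_line` columns.
#' @param seq The [pulse_sequence()] used in the experiment (defines the
#'   pulse minutes over which receptor intensity is summarized).
#' @return The filtered track table; a single-track replicate is kept with
#'   a warning.
#' @export
preselect_by_receptor <- function(tracks, seq) {
  stopifnot(inherits(seq, "pulse_sequence"))
  pm <- seq$pulse_minutes
  summaries <- tracks |>
    dplyr::group_by(.data$replicate_id, .data$cell_id) |>
    dplyr::summarise(
      receptor_summary = mean(.data$receptor_mean[.data$minute %in% pm]),
      w = dplyr::n(),
      cell_line = .data$cell_line[1], .groups = "drop")
  keep <- summaries |>
    dplyr::group_by(.data$replicate_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) {
        warning("replicate with a single track: kept without preselection",
                call. = FALSE)
        return(df[, c("cell_id", "receptor_summary")])
      }
      mu <- stats::weighted.mean(df$receptor_summary, df$w)
      sigma <- sqrt(sum(df$w * (df$receptor_summary - mu)^2) / sum(df$w))
      lims <- if (df$cell_line[1] == "STE1") {
        c(mu - 0.5 * sigma, mu + 2 * sigma)
      } else {
        c(mu, mu + 3 * sigma)
      }
      df[df$receptor_summary >= lims[1] & df$receptor_summary <= lims[2],
         c("cell_id", "receptor_summary")]
    }) |>
    dplyr::ungroup()
  dplyr::semi_join(tracks, keep, by = c("replicate_id", "cell_id"))
}

#' Responsiveness of a trajectory
#'
#' The standard deviation, across all time points k (not only pulse
#' minutes), of the 7-min change `y_k - y_{k+7}`. Being pulse-agnostic, it
#' can be supplied to the pulse decoder as a per-cell noise/variability
#' hint without leaking pulse timing. The population s.d. convention
#' (denominator n) is used; a single valid difference gives 0.
#'
#' @param y Numeric trajectory (per-minute values, `NA` allowed).
#' @param lag Difference lag in minutes (default 7).
#' @return A single number, or `NA` if fewer than one valid difference.
#' @export
responsiveness <- function(y, lag = 7) {
  n <- length(y)
  if (n < lag + 1) return(NA_real_)
  d <- y[seq_len(n - lag)] - y[seq_len(n - lag) + lag]
  d <- d[!is.na(d)]
  if (length(d) < 1) return(NA_real_)
  sqrt(sum((d - mean(d))^2) / length(d))
}

#' Per-pulse response amplitudes with interval-matched baseline correction
#'
#' The raw response amplitude of a cell at a pulse sent at minute t is the
#' trajectory log-change `y_{t+7} - y_t`. To remove the residual influence
#' of the previous pulse, the population baseline `baseline(L)` -- the mean
#' of `y_{p+L+7} - y_{p+L}` over all cells and all pulses p followed by an
#' interval of at least `L + 7` minutes, where L is the interval preceding
#' pulse t -- is subtracted.
#'
#' @param tracks A standardized track table.
#' @param seq The [pulse_sequence()].
#' @param offset Minutes after the pulse at which the response is read out
#'   (default 7, the ERK peak; use 2 for the calcineurin dip).
#' @return A tibble with one row per (cell, pulse): `replicate_id`,
#'   `cell_id`, `pulse_minute`, `preceding_interval`, `amplitude_raw`,
#'   `baseline`, `amplitude`. Pulses with missing trajectory values in the
#'   readout window have `NA` amplitude.
#' @export
response_amplitude <- function(tracks, seq, offset = 7) {
  stopifnot(inherits(seq, "pulse_sequence"))
  pm <- seq$pulse_minutes
  gaps_prev <- c(NA, diff(pm))
  gaps_next <- c(diff(pm), NA)
  ytab <- tracks |> dplyr::select("replicate_id", "cell_id", "minute", "y")

  lookup <- function(minutes) {
    tidyr::crossing(dplyr::distinct(ytab, .data$replicate_id, .data$cell_id),
                    pulse_minute = minutes)
  }
  # raw log-changes offset minutes after each pulse
  pulses <- lookup(pm) |>
    dplyr::left_join(
      tibble::tibble(pulse_minute = pm, preceding_interval = gaps_prev,
                     following_interval = gaps_next),
      by = "pulse_minute") |>
    dplyr::left_join(ytab, by = c("replicate_id", "cell_id",
                                  pulse_minute = "minute")) |>
    dplyr::rename(y0 = "y") |>
    dplyr::mutate(minute7 = .data$pulse_minute + offset) |>
    dplyr::left_join(ytab, by = c("replicate_id", "cell_id",
                                  minute7 = "minute")) |>
    dplyr::mutate(amplitude_raw = .data$y - .data$y0) |>
    dplyr::select(-"y", -"y0", -"minute7")

  # baseline(L): mean of y_{p+L+offset} - y_{p+L} over pulses p whose next
  # interval is at least L + offset
  Ls <- sort(unique(stats::na.omit(gaps_prev)))
  baseline_tbl <- purrr::map_dfr(Ls, function(L) {
    elig <- pm[!is.na(gaps_next) & gaps_next >= L + offset]
    if (length(elig) == 0) {
      return(tibble::tibble(preceding_interval = L, baseline = 0))
    }
    vals <- lookup(elig) |>
      dplyr::mutate(m1 = .data$pulse_minute + L,
                    m2 = .data$pulse_minute + L + offset) |>
      dplyr::left_join(ytab, by = c("replicate_id", "cell_id", m1 = "minute")) |>
      dplyr::rename(ya = "y") |>
      dplyr::left_join(ytab, by = c("replicate_id", "cell_id", m2 = "minute")) |>
      dplyr::mutate(d = .data$y - .data$ya)
    tibble::tibble(preceding_interval = L,
                   baseline = mean(vals$d, na.rm = TRUE))
  })

  pulses |>
    dplyr::left_join(baseline_tbl, by = "preceding_interval") |>
    dplyr::mutate(baseline = dplyr::coalesce(.data$baseline, 0),
                  amplitude = .data$amplitude_raw - .data$baseline) |>
    dplyr::select("replicate_id", "cell_id", "pulse_minute",
                  "preceding_interval", "amplitude_raw", "baseline",
                  "amplitude")
}

#' Per-cell summaries of standardized tracks
#'
#' Convenience table with one row per cell: track length, responsiveness,
#' mean response amplitude, receptor summary, position (at track midpoint
#' time), and condition covariates.
#'
#' @param tracks A standardized track table.
#' @param seq The [pulse_sequence()].
#' @return A tibble with one row per cell.
#' @export
summarize_tracks <- function(tracks, seq) {
  amp <- response_amplitude(tracks, seq) |>
    dplyr::group_by(.data$replicate_id, .data$cell_id) |>
    dplyr::summarise(mean_amplitude = mean(.data$amplitude, na.rm = TRUE),
                     .groups = "drop")
  pm <- seq$pulse_minutes
  tracks |>
    dplyr::group_by(.data$replicate_id, .data$cell_id) |>
    dplyr::summarise(
      track_length = dplyr::n(),
      s = responsiveness(.data$y),
      receptor_summary = mean(.data$receptor_mean[.data$minute %in% pm]),
      pos_x = .data$pos_x[ceiling(dplyr::n() / 2)],
      pos_y = .data$pos_y[ceiling(dplyr::n() / 2)],
      cell_line = .data$cell_line[1],
      alki_um = .data$alki_um[1], meki_um = .data$meki_um[1],
      calci_um = .data$calci_um[1],
      .groups = "drop") |>
    dplyr::left_join(amp, by = c("replicate_id", "cell_id"))
}
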