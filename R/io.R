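#' Read and write pulse-sequence files
#'
#' The writer emits the one-column list form (`pulse_minute`). The reader
#' auto-detects either that form or the two-column per-minute form
#' (`minute`, `pulse` in {0, 1}).
#'
#' @param seq A [pulse_sequence()].
#' @param path CSV file path.
#' @return `write_pulse_sequence()`: `path`, invisibly.
#' @export
write_pulse_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "pulse_sequence"))
  readr::write_csv(tibble::tibble(pulse_minute = seq$pulse_minutes), path)
  invisible(path)
}

#' @rdname write_pulse_sequence
#' @return `read_pulse_sequence()`: a [pulse_sequence()].
#' @export
read_pulse_sequence <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (all(c("minute", "pulse") %in% names(df))) {
    pulse_sequence(df$minute[df$pulse == 1], n_min = max(df$minute) + 1L)
  } else if ("pulse_minute" %in% names(df)) {
    pulse_sequence(df$pulse_minute)
  } else if (ncol(df) == 1) {
    pulse_sequence(df[[1]])
  } else {
    stop("unrecognized pulse-sequence file layout", call. = FALSE)
  }
}

#' Read and write protocol (interval distribution) files
#'
#' CSV with columns `interval_min`, `probability`.
#'
#' @param dist An [interval_distribution()].
#' @param path CSV file path.
#' @return `write_protocol()`: `path`, invisibly; `read_protocol()`: an
#'   [interval_distribution()].
#' @export
write_protocol <- function(dist, path) {
  stopifnot(inherits(dist, "interval_distribution"))
  readr::write_csv(tibble::tibble(interval_min = dist$interval,
                                  probability = dist$prob), path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  interval_distribution(df$interval_min, df$probability)
}

#' Write a datapoint table with a feature-statistics sidecar
#'
#' The datapoints go to CSV; the feature standardization statistics and
#' the (interval, last) group index go to a JSON sidecar
#' (`<path>.meta.json`).
#'
#' @param datapoints A datapoint tibble.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_datapoints <- function(datapoints, path) {
  readr::write_csv(datapoints, path)
  stats <- suppressWarnings(standardize_features(datapoints)$stats)
  groups <- datapoints |>
    dplyr::count(.data$interval, .data$last, name = "n")
  jsonlite::write_json(list(stats = stats, groups = groups),
                       paste0(path, ".meta.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_datapoints
#' @export
read_datapoints <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' QC report for the preprocessing filters
#'
#' Applies the short-track and receptor-preselection filters, recording
#' how many tracks each removes, and optionally writes the counts as JSON.
#'
#' @param tracks A standardized track table.
#' @param seq The [pulse_sequence()].
#' @param min_length Minimal track length (minutes).
#' @param json_path Optional path for the JSON QC report.
#' @return A list with `tracks` (filtered table) and `qc` (counts).
#' @export
preprocess_qc <- function(tracks, seq, min_length = 180, json_path = NULL) {
  n0 <- dplyr::n_distinct(tracks$replicate_id, tracks$cell_id)
  t1 <- filter_short_tracks(tracks, min_length)
  n1 <- dplyr::n_distinct(t1$replicate_id, t1$cell_id)
  t2 <- preselect_by_receptor(t1, seq)
  n2 <- dplyr::n_distinct(t2$replicate_id, t2$cell_id)
  qc <- list(n_tracks_input = n0,
             removed_short = n0 - n1,
             removed_receptor_preselection = n1 - n2,
             n_tracks_kept = n2)
  if (!is.null(json_path)) {
    jsonlite::write_json(qc, json_path, auto_unbox = TRUE)
  }
  list(tracks = t2, qc = qc)
}
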