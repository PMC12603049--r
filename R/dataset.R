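#' Extract decoder data points from standardized tracks
#'
#' Builds one data point per usable cell-minute k: the pulse indicator
#' `x_k`, the time since the previous pulse `last_k`, the interval
#' containing k, the trajectory-slice differences, the cell's
#' responsiveness `s`, and condition covariates. Slice modes:
#' \describe{
#'   \item{full}{`y_k..y_{k+6}` -> 6 differences (the default decoder);}
#'   \item{dip_only}{`y_k..y_{k+2}` -> 2 differences (calcineurin dip);}
#'   \item{peak_only}{`y_{k+6}..y_{k+12}` -> 6 differences (ERK peak).}
#' }
#' Differences `dy_i = y_{k+i} - y_{k+i-1}` (within the slice) abstract
#' from each cell's KTR expression level. A minute is usable when it lies
#' strictly after the first pulse, at or before the last pulse, and its
#' whole slice is inside the track with no missing values. Minutes during
#' the unstimulated warm-up (negative minutes) never qualify.
#'
#' @param tracks A standardized track table (see [standardize_tracks()]).
#' @param seq The [pulse_sequence()] on the same minute clock.
#' @param slice_mode `"full"`, `"dip_only"` or `"peak_only"`.
#' @param r Slice length in differences for the full mode (default 6).
#' @return A tibble with feature columns `dy1..dyn`, `log_last`, `s`,
#'   `cell_line_num`, `alki_um`, `meki_um`, `calci_um` and bookkeeping
#'   columns `replicate_id`, `cell_id`, `minute`, `x`, `last`, `interval`.
#' @export
extract_datapoints <- function(tracks, seq,
                               slice_mode = c("full", "dip_only", "peak_only"),
                               r = 6) {
  slice_mode <- match.arg(slice_mode)
  offs <- switch(slice_mode,
                 full = 0:r,
                 dip_only = 0:2,
                 peak_only = 6:12)
  ann <- annotate_sequence(seq)
  df <- tracks |>
    dplyr::inner_join(ann, by = "minute") |>
    dplyr::filter(.data$usable) |>
    dplyr::arrange(.data$replicate_id, .data$cell_id, .data$minute)

  # per-cell responsiveness from the full track
  s_tbl <- tracks |>
    dplyr::group_by(.data$replicate_id, .data$cell_id) |>
    dplyr::summarise(s = responsiveness(.data$y), .groups = "drop")
  df <- dplyr::left_join(df, s_tbl, by = c("replicate_id", "cell_id"))

  # trajectory values at k + offset, looked up within each cell's track
  ytab <- tracks |>
    dplyr::select("replicate_id", "cell_id", "minute", "y")
  for (i in seq_along(offs)) {
    df[[paste0(".y", i)]] <- dplyr::left_join(
      dplyr::mutate(df, .m = .data$minute + offs[i])[
        , c("replicate_id", "cell_id", ".m")],
      ytab, by = c("replicate_id", "cell_id", .m = "minute"))$y
  }
  ycols <- paste0(".y", seq_along(offs))
  ok <- stats::complete.cases(df[, c(ycols, "s")])
  df <- df[ok, ]
  for (i in 2:length(offs)) {
    df[[paste0("dy", i - 1)]] <- df[[ycols[i]]] - df[[ycols[i - 1]]]
  }
  df |>
    dplyr::mutate(log_last = log(.data$last),
                  cell_line_num = as.numeric(.data$cell_line == "BEAS2B")) |>
    dplyr::select("replicate_id", "cell_id", "minute", "x", "last",
                  "interval", dplyr::all_of(paste0("dy", seq_len(length(offs) - 1))),
                  "log_last", "s", "cell_line_num",
                  "alki_um", "meki_um", "calci_um")
}

#' Feature columns of a datapoint table
#' @param datapoints A datapoint tibble from [extract_datapoints()].
#' @return Character vector of feature column names (differences first).
#' @export
feature_columns <- function(datapoints) {
  c(grep("^dy[0-9]+$", names(datapoints), value = TRUE),
    "log_last", "s", "cell_line_num", "alki_um", "meki_um", "calci_um")
}

#' Dataset-wide feature standardization
#'
#' Centers and scales every feature column to zero mean and unit standard
#' deviation across the dataset. The statistics are returned so that they
#' can be stored with a trained classifier and reapplied verbatim at
#' inference. Zero-variance features are scaled by 1 with a warning.
#'
#' @param datapoints A datapoint tibble.
#' @return A list with `datapoints` (standardized) and `stats` (a tibble
#'   with `feature`, `mean`, `sd`).
#' @export
standardize_features <- function(datapoints) {
  feats <- feature_columns(datapoints)
  if (nrow(datapoints) == 0) stop("empty dataset", call. = FALSE)
  stats_tbl <- tibble::tibble(
    feature = feats,
    mean = purrr::map_dbl(feats, ~ mean(datapoints[[.x]])),
    sd = purrr::map_dbl(feats, ~ stats::sd(datapoints[[.x]])))
  if (any(stats_tbl$sd == 0 | is.na(stats_tbl$sd))) {
    warning("zero-variance feature(s) scaled by 1: ",
            paste(stats_tbl$feature[stats_tbl$sd == 0 | is.na(stats_tbl$sd)],
                  collapse = ", "), call. = FALSE)
    stats_tbl$sd[stats_tbl$sd == 0 | is.na(stats_tbl$sd)] <- 1
  }
  list(datapoints = apply_feature_stats(datapoints, stats_tbl),
       stats = stats_tbl)
}

#' @rdname standardize_features
#' @param stats A stats tibble previously returned by
#'   `standardize_features()`.
#' @export
apply_feature_stats <- function(datapoints, stats) {
  for (i in seq_len(nrow(stats))) {
    f <- stats$feature[i]
    datapoints[[f]] <- (datapoints[[f]] - stats$mean[i]) / stats$sd[i]
  }
  datapoints
}

#' Impute long intervals onto the measured 35-min interval
#'
#' Stimulation protocols under optimization may use intervals longer than
#' the longest measured one (35 min). Requested pairs
#' `(interval > 35, last)` are served with data from the 35-min interval at
#' an imputed time since pulse `last*`:
#' \itemize{
#'   \item if `last < 10`: `last* = last` (time since the pulse preserved);
#'   \item if `interval - last < 10`: `last* = 35 - (interval - last)`
#'     (time to the next pulse preserved);
#'   \item otherwise `last* = 10 + (last - 10) * (35 - 20) / (interval - 20)`
#'     (linear stretch of the interior).
#' }
#' The map is continuous across branches and keeps `last*` in `[1, 35]`.
#' The decoder still receives the true `last` as a feature and in its
#' prior; only the trajectory slice is imputed.
#'
#' @param interval Integer vector, all > 35.
#' @param last Integer vector, `1 <= last <= interval`.
#' @return A tibble with `interval_star` (always 35) and `last_star`
#'   (possibly fractional).
#' @export
impute_long_interval <- function(interval, last) {
  stopifnot(all(interval > 35), all(last >= 1), all(last <= interval))
  last_star <- ifelse(
    last < 10, last,
    ifelse(interval - last < 10, 35 - (interval - last),
           10 + (last - 10) * (35 - 20) / (interval - 20)))
  tibble::tibble(interval_star = 35, last_star = last_star)
}

# Build the sampling plan for a candidate protocol against a dataset:
# one row per (interval, last) pair of the protocol's joint distribution,
# with the dataset group that serves it (imputing intervals > 35 and
# falling back to the Manhattan-nearest non-empty group when a pair has no
# data). Groups are keyed by interval * 1000 + last.
build_sampling_plan <- function(datapoints, protocol, impute_above = 35,
                                warn_fallback = TRUE) {
  joint <- joint_interval_last(protocol)
  keys_data <- unique(datapoints$interval * 1000L + datapoints$last)
  grp_interval <- keys_data %/% 1000L
  grp_last <- keys_data %% 1000L

  fetch_interval <- joint$interval
  fetch_last <- joint$last
  long <- fetch_interval > impute_above
  if (any(long)) {
    imp <- impute_long_interval(fetch_interval[long], fetch_last[long])
    fetch_interval[long] <- imp$interval_star
    fetch_last[long] <- as.integer(round(imp$last_star))
  }
  want <- fetch_interval * 1000L + fetch_last
  missing <- !(want %in% keys_data)
  if (any(missing)) {
    if (warn_fallback) {
      warning(sum(missing), " protocol (interval, last) pair(s) without data;",
              " borrowing from nearest groups", call. = FALSE)
    }
    for (j in which(missing)) {
      d <- abs(grp_interval - fetch_interval[j]) + abs(grp_last - fetch_last[j])
      k <- which.min(d)
      fetch_interval[j] <- grp_interval[k]
      fetch_last[j] <- grp_last[k]
    }
    want <- fetch_interval * 1000L + fetch_last
  }
  tibble::tibble(
    interval = joint$interval, last = joint$last, prob = joint$prob,
    x = as.integer(joint$last == joint$interval),
    fetch_key = want)
}

# Row indices of `datapoints` per (interval, last) group key.
group_row_index <- function(datapoints) {
  key <- datapoints$interval * 1000L + datapoints$last
  split(seq_along(key), key)
}

#' Sample a protocol-weighted minibatch of data points
#'
#' Draws `(interval, last)` pairs from the joint stationary distribution of
#' the assumed protocol, then draws data points uniformly with replacement
#' from the matching dataset groups. Pairs with intervals beyond the
#' measured range are served by long-interval imputation
#' ([impute_long_interval()]); pairs without any data borrow from the
#' nearest non-empty group in Manhattan distance (with a warning). In the
#' returned batch, `x`, `last`, `interval` and `log_last` are those of the
#' *requested* pair (the trajectory features come from the fetched group).
#'
#' @param datapoints A datapoint tibble.
#' @param protocol The assumed [stimulation_protocol()].
#' @param batch_size Number of points to draw (default 1e4).
#' @param seed Optional integer seed.
#' @return A datapoint tibble of `batch_size` rows.
#' @export
sample_minibatch <- function(datapoints, protocol, batch_size = 10000,
                             seed = NULL) {
  if (nrow(datapoints) == 0) stop("empty dataset", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  plan <- build_sampling_plan(datapoints, protocol)
  gindex <- group_row_index(datapoints)
  counts <- as.vector(stats::rmultinom(1, batch_size, plan$prob))
  take <- counts > 0
  rows <- purrr::map2(plan$fetch_key[take], counts[take], function(k, n) {
    idx <- gindex[[as.character(k)]]
    idx[sample.int(length(idx), n, replace = TRUE)]
  })
  batch <- datapoints[unlist(rows), ]
  batch$interval <- rep(plan$interval[take], counts[take])
  batch$last <- rep(plan$last[take], counts[take])
  batch$x <- rep(plan$x[take], counts[take])
  batch$log_last <- log(batch$last)
  batch
}
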