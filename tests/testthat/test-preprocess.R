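toy_track <- function(y, cell_id = "c1", replicate_id = "R1", bg = 0,
                      frame = 100) {
  tibble::tibble(replicate_id = replicate_id, cell_id = cell_id,
                 minute = seq_along(y) - 1,
                 nuclear_mean = bg + (frame - bg) * exp(-y),
                 frame_mean = frame)
}

test_that("track standardization computes -log nuclear/frame after background", {
  raw <- tibble::tibble(replicate_id = "R1", cell_id = "c1", minute = 0:2,
                        nuclear_mean = c(100, 100 / exp(1), 110),
                        frame_mean = c(100, 100, 110))
  tr0 <- standardize_tracks(raw, background = 0)
  expect_equal(tr0$y[1], 0)
  expect_equal(tr0$y[2], 1)
  tr10 <- standardize_tracks(raw[3, ], background = 10)
  expect_equal(tr10$y, 0)
  # non-positive background-subtracted intensity flags the minute missing
  bad <- tibble::tibble(replicate_id = "R1", cell_id = "c1", minute = 0,
                        nuclear_mean = 5, frame_mean = 100)
  expect_true(is.na(standardize_tracks(bad, background = 10)$y))
})

test_that("per-replicate background values are honored", {
  raw <- dplyr::bind_rows(
    tibble::tibble(replicate_id = "R1", cell_id = "a", minute = 0,
                   nuclear_mean = 110, frame_mean = 110),
    tibble::tibble(replicate_id = "R2", cell_id = "b", minute = 0,
                   nuclear_mean = 110, frame_mean = 110))
  bg <- tibble::tibble(replicate_id = c("R1", "R2"), background = c(10, 60))
  tr <- standardize_tracks(raw, background = bg)
  expect_equal(tr$y, c(0, 0))
})

test_that("short tracks are removed with an inclusive 180-min boundary", {
  tr <- dplyr::bind_rows(toy_track(rep(0, 179), "short"),
                         toy_track(rep(0, 180), "exact"),
                         toy_track(rep(0, 200), "long"))
  kept <- filter_short_tracks(standardize_tracks(tr), min_length = 180)
  expect_setequal(unique(kept$cell_id), c("exact", "long"))
  empty <- filter_short_tracks(standardize_tracks(tr)[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("receptor preselection applies cell-line-specific weighted ranges", {
  sq <- pulse_sequence(c(0, 10, 20), n_min = 30)
  make <- function(ids, receptor, cell_line) {
    purrr::map_dfr(seq_along(ids), function(i) {
      tibble::tibble(replicate_id = "R1", cell_id = ids[i], minute = 0:29,
                     y = 0, receptor_mean = receptor[i],
                     cell_line = cell_line)
    })
  }
  # equal track lengths: mu = mean, sigma = population sd
  rec <- c(100, 110, 120, 130, 140)
  mu <- mean(rec); sigma <- sqrt(mean((rec - mu)^2))
  beas <- make(paste0("c", 1:5), rec, "BEAS2B")
  kept_beas <- preselect_by_receptor(beas, sq)
  expect_setequal(unique(kept_beas$cell_id),
                  paste0("c", which(rec >= mu & rec <= mu + 3 * sigma)))
  # a cell just below mu is discarded for BEAS2B
  beas2 <- make(paste0("c", 1:5), c(mu - 0.01 * sigma, 115, 125, 135, 145),
                "BEAS2B")
  kept2 <- preselect_by_receptor(beas2, sq)
  expect_false("c1" %in% kept2$cell_id)
  # STE1 keeps a cell at mu (range extends 0.5 sigma below)
  ste <- make(paste0("s", 1:5), rec, "STE1")
  kept_ste <- preselect_by_receptor(ste, sq)
  expect_true(paste0("s", which(rec == 120)) %in% kept_ste$cell_id)
  # sigma = 0: everything kept; filter never adds tracks
  same <- make(paste0("z", 1:4), rep(100, 4), "BEAS2B")
  expect_setequal(unique(preselect_by_receptor(same, sq)$cell_id),
                  paste0("z", 1:4))
  expect_lte(dplyr::n_distinct(kept_beas$cell_id), 5L)
  # single track: kept with a warning
  single <- make("only", 100, "BEAS2B")
  expect_warning(out <- preselect_by_receptor(single, sq), "single")
  expect_equal(unique(out$cell_id), "only")
})

test_that("responsiveness is the population sd of 7-min differences", {
  expect_equal(responsiveness(rep(1, 50)), 0)
  expect_equal(responsiveness(seq(0, 49)), 0)        # constant slope
  expect_equal(responsiveness(c(0, 0, 0, 0, 0, 0, 0, 1)), 0)  # one diff
  expect_true(is.na(responsiveness(rep(0, 5))))
  y <- rep(0, 14); y[8] <- 1       # one step: differences vary
  expect_gt(responsiveness(y), 0)
})

test_that("response amplitude subtracts the interval-matched baseline", {
  # flat track, zero baseline
  sq <- pulse_sequence(c(0, 10, 30), n_min = 45)
  flat <- standardize_tracks(toy_track(rep(0.4, 45)))
  amp <- response_amplitude(flat, sq)
  expect_equal(amp$amplitude[amp$pulse_minute == 10], 0)

  # arithmetic: raw 0.4, baseline 0.1 -> 0.3 (constructed two-cell toy)
  # cell A responds at pulse 10 (y jumps by 0.4 between minutes 10 and 17)
  yA <- rep(0, 45); yA[18:45] <- 0.4
  # both cells drift by 0.1 between minutes 20 and 27 -> baseline(10) = 0.1
  yB <- rep(0, 45)
  drift <- rep(0, 45); drift[28:45] <- 0.1
  tr <- dplyr::bind_rows(toy_track(yA + drift, "A"), toy_track(yB + drift, "B"))
  tr <- standardize_tracks(tr)
  amp2 <- response_amplitude(tr, sq)
  a10 <- amp2[amp2$pulse_minute == 10 & amp2$cell_id == "A", ]
  # pulse 10 has preceding interval L = 10; eligible baseline pulses are
  # those followed by >= 17-min intervals: only the pulse at 10 itself
  # (next interval 20); baseline = mean change between minutes 20 and 27
  expect_equal(a10$baseline, 0.1, tolerance = 1e-12)
  expect_equal(a10$amplitude_raw, 0.4, tolerance = 1e-12)
  expect_equal(a10$amplitude, 0.3, tolerance = 1e-12)
})

test_that("baseline eligibility excludes pulses with too-short next intervals", {
  # pulses 0, 10, 30: for L = 20 (pulse 30), eligibility needs a following
  # interval >= 27 min -> no pulse qualifies -> baseline defaults to 0
  sq <- pulse_sequence(c(0, 10, 30), n_min = 45)
  y <- cumsum(stats::rnorm(45, 0, 0.01))
  tr <- standardize_tracks(toy_track(y))
  amp <- response_amplitude(tr, sq)
  a30 <- amp[amp$pulse_minute == 30, ]
  expect_equal(a30$baseline, 0)
})

test_that("pure-noise populations have near-zero mean amplitude", {
  cfg <- simulation_config(n_cells = 150, fraction_transmitting = 0, seed = 13)
  raw <- simulate_population(cfg, fx_seq_small)
  tr <- standardize_tracks(raw, background = cfg$background)
  amp <- response_amplitude(tr, fx_seq_small)
  expect_lt(abs(mean(amp$amplitude, na.rm = TRUE)), 0.01)
})

test_that("qc report counts removals by filter", {
  out <- preprocess_qc(fx_tracks, fx_seq_small, min_length = 180)
  expect_equal(out$qc$n_tracks_input, 40L)
  expect_equal(out$qc$n_tracks_input - out$qc$removed_short -
                 out$qc$removed_receptor_preselection,
               out$qc$n_tracks_kept)
  expect_lte(out$qc$n_tracks_kept, out$qc$n_tracks_input)
})
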