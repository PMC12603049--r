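test_that("mean logit update table groups correctly and flags signal structure", {
  ut <- mean_logit_update(fx_model, fx_dp)
  # counts equal the dataset's group sizes
  grp <- dplyr::count(fx_dp, interval, last)
  chk <- dplyr::inner_join(ut, grp, by = c("interval", "last"))
  expect_equal(nrow(chk), nrow(ut))
  expect_equal(chk$n.x, chk$n.y)
  # diagonal entries correspond to pulse points
  diag_curve <- diagonal_update_curve(ut)
  expect_true(all(diag_curve$interval %in% fx_emp$interval))
  # informative fixture: diagonal updates at long intervals are positive,
  # long-last off-diagonal entries are negative on average
  long <- diag_curve$mean_u[diag_curve$interval >= 20]
  expect_gt(mean(long), 0)
  off <- ut[ut$last != ut$interval & ut$last >= 15, ]
  expect_lt(stats::weighted.mean(off$mean_u, off$n), 0)
})

test_that("update-table consistency: group means reproduce the population bitrate", {
  ev <- pulsebit:::evaluate_datapoints(fx_dp, fx_model, fx_proto_small)
  by_grp <- ev |>
    dplyr::group_by(interval, last) |>
    dplyr::summarise(mi = mean(info_bits), n = dplyr::n(), .groups = "drop")
  b_from_groups <- 60 * sum(by_grp$mi * by_grp$n) / sum(by_grp$n)
  expect_equal(b_from_groups, glance(fx_report)$bitrate, tolerance = 1e-12)
})

test_that("no-information data yield near-zero updates everywhere", {
  cfg <- simulation_config(n_cells = 60, fraction_transmitting = 0, seed = 41)
  raw <- simulate_population(cfg, fx_seq_small)
  tr <- standardize_tracks(raw, background = cfg$background)
  dp <- extract_datapoints(tr, fx_seq_small)
  m <- train_pulse_classifier(dp, fx_proto_small, steps = 300, seed = 3)
  ut <- mean_logit_update(m, dp)
  expect_lt(stats::weighted.mean(abs(ut$mean_u), ut$n), 0.2)
})

test_that("effective refractory time interpolates the half-asymptote crossing", {
  # step curve 0 -> A at 10 min
  step_curve <- tibble::tibble(interval = c(5, 9, 10, 15, 20, 25, 30, 35),
                               mean_u = c(0, 0, 2, 2, 2, 2, 2, 2))
  expect_equal(effective_refractory_time(step_curve)$refractory_min, 9.5)
  expect_equal(effective_refractory_time(step_curve)$status, "ok")
  # explicit interpolation case: 5 -> 0, 10 -> A/2, 15 -> A, plateau A
  interp <- tibble::tibble(interval = c(5, 10, 15, 20, 25, 30, 35),
                           mean_u = c(0, 1, 2, 2, 2, 2, 2))
  expect_equal(effective_refractory_time(interp)$refractory_min, 10)
  # flat positive curve: refractory below the tested range
  flat <- tibble::tibble(interval = seq(5, 35, 5), mean_u = 1.5)
  expect_equal(effective_refractory_time(flat)$status, "below support")
  # non-positive asymptote: undefined
  dead <- tibble::tibble(interval = seq(5, 35, 5), mean_u = -0.1)
  expect_equal(effective_refractory_time(dead)$status, "undefined")
})

test_that("simulated refractory channel crosses near its configured half-time", {
  # high-SNR peak-only channel with 8.5-min recovery half-time: the
  # detection-certainty curve should cross half-asymptote within a few
  # minutes of it
  sq <- realize_pulse_sequence(fx_dist, 1020)
  proto <- stimulation_protocol(empirical_interval_distribution(sq))
  cfg <- simulation_config(n_cells = 50, fraction_transmitting = 1,
                           peak_gain = 0.8, dip_gain = 0, noise_sd = 0.03,
                           seed = 19)
  raw <- simulate_population(cfg, sq)
  tr <- standardize_tracks(raw, background = cfg$background)
  dp <- extract_datapoints(tr, sq)
  m <- train_pulse_classifier(dp, proto, steps = 500, seed = 2)
  eft <- effective_refractory_time(diagonal_update_curve(
    mean_logit_update(m, dp)))
  expect_equal(eft$status, "ok")
  expect_gt(eft$refractory_min, 5)
  expect_lt(eft$refractory_min, 14)
})

test_that("neighbor transmission probabilities match hand enumeration", {
  # collinear toy: positions 0,1,2,3 with flags T,T,N,N
  toy <- tibble::tibble(pos_x = c(0, 1, 2, 3), pos_y = 0,
                        transmitting = c(TRUE, TRUE, FALSE, FALSE))
  nb <- neighbor_transmission_probability(toy, k_max = 1)
  # anchors 1,2 (T): nearest neighbors are 2 (T) and 1 (T, tie to 1 by order)
  expect_equal(nb$prob[nb$anchor == "transmitting"], 1)
  # anchors 3,4 (N): nearest neighbors are 2 (T, tie) and 3 (N)
  expect_equal(nb$prob[nb$anchor == "non-transmitting"], 0.5)
  # all transmitting: probability 1 for all k
  allT <- tibble::tibble(pos_x = stats::runif(10), pos_y = stats::runif(10),
                         transmitting = TRUE)
  nbT <- neighbor_transmission_probability(allT, k_max = 3)
  expect_equal(nbT$prob[nbT$anchor == "transmitting"], rep(1, 3))
})

test_that("shuffled labels give flat neighbor curves within binomial error", {
  set.seed(12)
  n <- 300
  cells <- tibble::tibble(pos_x = stats::runif(n, 0, 1000),
                          pos_y = stats::runif(n, 0, 1000),
                          transmitting = sample(c(TRUE, FALSE), n,
                                                replace = TRUE,
                                                prob = c(0.6, 0.4)))
  nb <- neighbor_transmission_probability(cells, k_max = 6)
  frac <- mean(cells$transmitting)
  tol <- 4 * sqrt(frac * (1 - frac) / (n * 0.4))
  expect_true(all(abs(nb$prob - frac) < tol))
})

test_that("condition summaries report means and SEMs per condition", {
  rs <- tibble::tibble(
    condition = c("A", "A", "A", "B"),
    replicate_id = c("R1", "R2", "R3", "R1"),
    bitrate = c(5, 5, 5, 7),
    fraction = c(0.6, 0.7, 0.65, 0.2))
  cs <- condition_summary(rs)
  expect_equal(cs$bitrate_mean, c(5, 7))
  expect_equal(cs$bitrate_sem, c(0, NA))          # identical reps; single rep
  expect_equal(cs$fraction_sem[1], stats::sd(c(0.6, 0.7, 0.65)) / sqrt(3))
})

test_that("plot constructors return ggplot objects", {
  expect_s3_class(autoplot(fx_emp), "ggplot")
  expect_s3_class(autoplot(fx_report), "ggplot")
  ut <- mean_logit_update(fx_model, fx_dp[1:2000, ])
  expect_s3_class(plot_update_table(ut), "ggplot")
})
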