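test_that("gamma interval distribution matches Gamma mode, mean, and degenerate cases", {
  d <- gamma_interval_distribution(shape = 4, scale = 5,
                                   support_min = 5, support_max = 35)
  expect_equal(d$interval[which.max(d$prob)], 15L)  # mode = (shape-1)*scale
  wide <- gamma_interval_distribution(shape = 4, scale = 5,
                                      support_min = 1, support_max = 300)
  expect_equal(mean_interval(wide), 4 * 5, tolerance = 1e-3)
  deg <- gamma_interval_distribution(support_min = 10, support_max = 10)
  expect_equal(deg$prob, 1)
  expect_error(gamma_interval_distribution(shape = -1), "positive")
})

test_that("interval_distribution validates its invariants", {
  expect_error(interval_distribution(c(5, 3), c(0.5, 0.5)), "increasing")
  expect_error(interval_distribution(c(1, 2), c(0.5, -0.1)), "non-negative")
  expect_error(interval_distribution(integer(0), numeric(0)), "empty")
  d <- interval_distribution(c(2, 4), c(2, 6))
  expect_equal(sum(d$prob), 1)
  expect_error(interval_distribution(c(1, 2), c(0.6, 0.6), normalize = FALSE),
               "sum to 1")
})

test_that("entropy rate: Bernoulli(1/2) pulses give 60 bit/h, degenerate gives 0", {
  expect_equal(entropy_rate(bernoulli_interval_distribution(0.5)), 60)
  expect_equal(entropy_rate(interval_distribution(10, 1)), 0)
})

test_that("no 1-minute-resolution protocol exceeds 60 bit/h", {
  set.seed(1)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    d <- interval_distribution(sort(sample(1:60, n)), stats::runif(n))
    expect_lte(entropy_rate(d), 60 + 1e-9)
  }
})

test_that("hazard is the renewal conditional pulse probability", {
  # memoryless: geometric intervals have constant hazard
  g <- bernoulli_interval_distribution(0.3, 40)
  h <- hazard_from_distribution(g)
  expect_equal(h$hazard[1:30], rep(0.3, 30), tolerance = 1e-9)
  # degenerate at 10
  h10 <- hazard_from_distribution(interval_distribution(10, 1))
  expect_equal(h10$hazard, c(rep(0, 9), 1))
  # two-point distribution, by direct summation
  h2 <- hazard_from_distribution(interval_distribution(c(5, 10), c(0.5, 0.5)))
  expect_equal(h2$hazard[5], 0.5)
  expect_equal(h2$hazard[10], 1)
  expect_equal(h2$hazard[c(1:4, 6:9)], rep(0, 8))
})

test_that("hazard reconstructs the interval distribution exactly", {
  set.seed(2)
  for (i in 1:10) {
    n <- sample(2:15, 1)
    d <- interval_distribution(sort(sample(1:40, n)), stats::runif(n))
    h <- hazard_from_distribution(d)$hazard
    p_rec <- h * cumprod(c(1, 1 - h[-length(h)]))
    expect_equal(p_rec[d$interval], d$prob, tolerance = 1e-12)
  }
})

test_that("prior clipping keeps hazard logits finite", {
  proto <- stimulation_protocol(interval_distribution(c(5, 10), c(.5, .5)),
                                prior_clip = 1e-6)
  pr <- protocol_prior(proto, c(1, 5, 10, 50))
  expect_true(all(pr > 0 & pr < 1))
  expect_equal(pr[3], 1 - 1e-6)   # hazard 1 at max support, clipped
  expect_equal(pr[1], 1e-6)       # below support: hazard 0, clipped
  expect_true(all(is.finite(stats::qlogis(pr))))
})

test_that("realized sequences respect budget, repetition, and ordering rules", {
  gaps <- diff(fx_seq$pulse_minutes)
  expect_lte(sum(gaps), 1020)
  tab <- table(gaps)
  short <- as.integer(names(tab)) <= 12
  expect_true(all(tab[short] >= 2))
  # determinism
  expect_identical(realize_pulse_sequence(fx_dist, 1020)$pulse_minutes,
                   fx_seq$pulse_minutes)
  # repeated lengths are preceded by intervals spread across the
  # distribution: sorted predecessors increase and straddle the median
  cdf <- cumsum(fx_dist$prob)
  med <- fx_dist$interval[which(cdf >= 0.5)[1]]
  for (len in as.integer(names(tab[tab >= 3]))) {
    pos <- which(gaps == len)
    preds <- gaps[pos[pos > 1] - 1]
    if (length(preds) >= 3) {
      expect_true(all(diff(sort(preds)) > 0))
      expect_lt(min(preds), med)
      expect_gte(max(preds), med)
    }
  }
})

test_that("degenerate distribution realizes evenly spaced pulses", {
  sq <- realize_pulse_sequence(interval_distribution(10, 1), 100)
  expect_equal(diff(sq$pulse_minutes), rep(10, 10))
  expect_error(realize_pulse_sequence(interval_distribution(10, 1), 15),
               "budget")
})

test_that("sequence annotation has the diagonal property and flags edges", {
  sq <- pulse_sequence(c(0, 10))
  ann <- annotate_sequence(sq)
  m10 <- ann[ann$minute == 10, ]
  expect_equal(c(m10$x, m10$last, m10$interval), c(1, 10, 10))
  m4 <- ann[ann$minute == 4, ]
  expect_equal(c(m4$x, m4$last, m4$interval), c(0, 4, 10))
  expect_false(ann$usable[ann$minute == 0])

  ann2 <- annotate_sequence(fx_seq)
  us <- ann2[ann2$usable, ]
  expect_true(all((us$x == 1) == (us$last == us$interval)))
  expect_error(annotate_sequence(pulse_sequence(5)), "two pulses")
})

test_that("chain-rule entropy rate matches brute-force sequence enumeration", {
  dists <- list(interval_distribution(c(2, 3), c(0.6, 0.4)),
                interval_distribution(c(1, 2, 4), c(0.3, 0.5, 0.2)),
                interval_distribution(c(2, 5), c(0.5, 0.5)))
  for (d in dists) {
    rate <- entropy_rate(d) / 60      # bits per minute
    H14 <- brute_force_sequence_entropy(d, 14)
    H7 <- brute_force_sequence_entropy(d, 7)
    # telescoped conditional entropy over minutes 8..14 approaches the
    # renewal entropy rate up to the finite-horizon discretization
    expect_equal((H14 - H7) / 7, rate, tolerance = 0.015)
  }
})

test_that("joint (interval, last) distribution is the stationary renewal view", {
  j10 <- joint_interval_last(interval_distribution(10, 1))
  expect_equal(nrow(j10), 10L)
  expect_equal(j10$prob, rep(0.1, 10))
  j <- joint_interval_last(fx_protocol)
  expect_equal(sum(j$prob), 1, tolerance = 1e-9)
  diag_mass <- sum(j$prob[j$interval == j$last])
  expect_equal(diag_mass, 1 / mean_interval(fx_emp), tolerance = 1e-12)
})

test_that("protocol and sequence files round-trip", {
  f1 <- tempfile(fileext = ".csv")
  write_protocol(fx_emp, f1)
  d2 <- read_protocol(f1)
  expect_equal(d2$interval, fx_emp$interval)
  expect_equal(d2$prob, fx_emp$prob, tolerance = 1e-12)

  f2 <- tempfile(fileext = ".csv")
  write_pulse_sequence(fx_seq, f2)
  expect_identical(read_pulse_sequence(f2)$pulse_minutes, fx_seq$pulse_minutes)
  # two-column per-minute form
  ann <- annotate_sequence(fx_seq)
  f3 <- tempfile(fileext = ".csv")
  readr::write_csv(data.frame(minute = ann$minute, pulse = ann$x), f3)
  expect_identical(read_pulse_sequence(f3)$pulse_minutes, fx_seq$pulse_minutes)
})
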