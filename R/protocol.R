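#' Interval distributions for pulsatile stimulation protocols
#'
#' An interval distribution assigns a probability to each admissible gap
#' length (in whole minutes) between consecutive stimulation pulses. Under
#' interval encoding the pulse train is a renewal process: successive
#' intervals are drawn independently from this distribution, and all
#' information carried by the train lives in the interval lengths.
#'
#' @param interval Integer vector of interval lengths in minutes; strictly
#'   increasing, all >= 1.
#' @param prob Numeric vector of probabilities, same length as `interval`,
#'   all >= 0. Renormalized to sum to one when `normalize = TRUE`.
#' @param normalize Renormalize `prob` to sum to 1 (default `TRUE`). With
#'   `normalize = FALSE` the probabilities must already sum to 1 within 1e-9.
#'
#' @return A tibble of class `interval_distribution` with columns `interval`
#'   and `prob`.
#' @examples
#' d <- interval_distribution(c(5, 10), c(0.5, 0.5))
#' mean_interval(d)
#' entropy_rate(d)
#' @export
interval_distribution <- function(interval, prob, normalize = TRUE) {
  if (length(interval) == 0L) stop("empty interval support", call. = FALSE)
  if (length(interval) != length(prob)) {
    stop("`interval` and `prob` must have the same length", call. = FALSE)
  }
  if (any(interval < 1) || any(interval != round(interval))) {
    stop("interval support must consist of positive whole minutes", call. = FALSE)
  }
  if (is.unsorted(interval, strictly = TRUE)) {
    stop("interval support must be strictly increasing", call. = FALSE)
  }
  if (any(prob < 0)) stop("probabilities must be non-negative", call. = FALSE)
  s <- sum(prob)
  if (s <= 0) stop("probabilities must not all be zero", call. = FALSE)
  if (normalize) {
    prob <- prob / s
  } else if (abs(s - 1) > 1e-9) {
    stop("probabilities must sum to 1 within 1e-9 (or set normalize = TRUE)",
         call. = FALSE)
  }
  out <- tibble::tibble(interval = as.integer(interval), prob = as.numeric(prob))
  class(out) <- c("interval_distribution", class(out))
  out
}

#' @export
print.interval_distribution <- function(x, ...) {
  cat(sprintf(
    "<interval_distribution> %d lengths on [%d, %d] min | mean %.2f min | %.2f bit/pulse | %.2f bit/h\n",
    nrow(x), min(x$interval), max(x$interval), mean_interval(x),
    interval_entropy(x), entropy_rate(x)))
  NextMethod()
}

#' Gamma-shaped interval distribution on a discrete support
#'
#' Discretizes a Gamma density at whole minutes on
#' `[support_min, support_max]` and renormalizes. A Gamma with shape 4 and
#' scale 5 min on 5--35 min is the design used for the experimental
#' stimulation protocol: broad enough to probe many interval lengths while
#' keeping most mass above the pathway's refractory time.
#'
#' @param shape,scale Gamma shape (dimensionless) and scale (minutes), both
#'   positive.
#' @param support_min,support_max Smallest/largest admissible interval
#'   (minutes).
#' @return An [interval_distribution()].
#' @export
gamma_interval_distribution <- function(shape = 4, scale = 5,
                                        support_min = 5, support_max = 35) {
  if (shape <= 0 || scale <= 0) {
    stop("`shape` and `scale` must be positive", call. = FALSE)
  }
  if (support_min < 1 || support_max < support_min) {
    stop("invalid support range", call. = FALSE)
  }
  L <- seq.int(support_min, support_max)
  interval_distribution(L, stats::dgamma(L, shape = shape, scale = scale))
}

#' Summary functionals of an interval distribution
#'
#' `mean_interval()` is the expected interval length E[L] in minutes;
#' `interval_entropy()` is the Shannon entropy H(L) in bits per pulse;
#' `entropy_rate()` converts to bits per hour, `60 * H(L) / E[L]`, which for
#' a renewal pulse train equals the per-minute conditional entropy rate of
#' the induced binary process. A per-minute Bernoulli(1/2) train (geometric
#' intervals with q = 1/2) attains the 1-minute-resolution maximum, 60 bit/h.
#'
#' @param dist An [interval_distribution()].
#' @return A single number.
#' @export
mean_interval <- function(dist) {
  stopifnot(inherits(dist, "interval_distribution"))
  sum(dist$interval * dist$prob)
}

#' @rdname mean_interval
#' @export
interval_entropy <- function(dist) {
  stopifnot(inherits(dist, "interval_distribution"))
  p <- dist$prob[dist$prob > 0]
  -sum(p * log2(p))
}

#' @rdname mean_interval
#' @export
entropy_rate <- function(dist) {
  60 * interval_entropy(dist) / mean_interval(dist)
}

#' Geometric interval distribution induced by per-minute Bernoulli pulses
#'
#' Pulses occurring independently each minute with probability `q` induce
#' geometric intervals `p(l) = q (1-q)^(l-1)`. The support is truncated at
#' `max_interval` (remaining tail mass assigned to the last length), which
#' leaves the entropy rate unchanged to double precision for
#' `max_interval >= 60`.
#'
#' @param q Per-minute pulse probability in (0, 1).
#' @param max_interval Truncation length in minutes.
#' @return An [interval_distribution()].
#' @export
bernoulli_interval_distribution <- function(q = 0.5, max_interval = 120) {
  stopifnot(q > 0, q < 1, max_interval >= 2)
  l <- seq_len(max_interval)
  p <- q * (1 - q)^(l - 1)
  p[max_interval] <- (1 - q)^(max_interval - 1)
  interval_distribution(l, p, normalize = FALSE)
}

#' Hazard (per-minute prior pulse probability) of an interval distribution
#'
#' For a renewal pulse train the probability of a pulse at minute k depends
#' only on the time `last` elapsed since the previous pulse:
#' `h(l) = p(L = l) / P(L >= l)`. The hazard is 0 below the support minimum
#' and reaches exactly 1 at the largest supported interval. This is the
#' decoder's prior: the best per-minute pulse prediction from the protocol
#' alone.
#'
#' @param dist An [interval_distribution()].
#' @return A tibble with columns `last` (1..max support) and `hazard`.
#' @export
hazard_from_distribution <- function(dist) {
  stopifnot(inherits(dist, "interval_distribution"))
  max_l <- max(dist$interval)
  p <- numeric(max_l)
  p[dist$interval] <- dist$prob
  surv <- rev(cumsum(rev(p)))      # P(L >= l)
  h <- ifelse(surv > 0, p / surv, 0)
  tibble::tibble(last = seq_len(max_l), hazard = h)
}

#' Stimulation protocol: interval distribution plus clipped hazard prior
#'
#' Bundles an interval distribution with its hazard and a clipping constant
#' used to keep prior logits finite (the hazard is exactly 1 at the maximal
#' interval, and 0 below the support minimum).
#'
#' @param dist An [interval_distribution()].
#' @param prior_clip Clipping half-width; hazards are clipped into
#'   `[prior_clip, 1 - prior_clip]` before logit transforms. Default 1e-6.
#' @return An object of class `stimulation_protocol`.
#' @export
stimulation_protocol <- function(dist, prior_clip = 1e-6) {
  stopifnot(inherits(dist, "interval_distribution"),
            prior_clip > 0, prior_clip < 0.5)
  structure(
    list(dist = dist, hazard = hazard_from_distribution(dist),
         prior_clip = prior_clip),
    class = "stimulation_protocol")
}

#' @export
print.stimulation_protocol <- function(x, ...) {
  cat("<stimulation_protocol>\n")
  print(x$dist)
  invisible(x)
}

#' Coerce to a stimulation protocol
#' @param x An `interval_distribution` or `stimulation_protocol`.
#' @param prior_clip Clip used when coercing a bare distribution.
#' @return A `stimulation_protocol`.
#' @export
as_stimulation_protocol <- function(x, prior_clip = 1e-6) {
  if (inherits(x, "stimulation_protocol")) return(x)
  if (inherits(x, "interval_distribution")) {
    return(stimulation_protocol(x, prior_clip = prior_clip))
  }
  stop("cannot coerce to stimulation_protocol", call. = FALSE)
}

#' Clipped prior pulse probability for given times since the last pulse
#'
#' Looks up the protocol hazard at `last` and clips into
#' `[prior_clip, 1 - prior_clip]`. Values of `last` beyond the protocol's
#' maximal interval are clamped to the maximum (hazard 1 before clipping).
#'
#' @param protocol A [stimulation_protocol()] (or interval distribution).
#' @param last Integer vector of minutes since the previous pulse (>= 1).
#' @return Numeric vector of prior probabilities in (0, 1).
#' @export
protocol_prior <- function(protocol, last) {
  protocol <- as_stimulation_protocol(protocol)
  h <- protocol$hazard$hazard
  idx <- pmin(pmax(as.integer(last), 1L), length(h))
  pmin(pmax(h[idx], protocol$prior_clip), 1 - protocol$prior_clip)
}

#' Realize a pulse sequence from an interval distribution
#'
#' Chooses integer interval counts that best match the distribution within a
#' time budget, forces every "short" interval length (at or below
#' `short_cutoff`) in the support to occur at least twice, and orders the
#' intervals so that the m-th occurrence of a repeated length is preceded by
#' an interval close to the m/(c+1) quantile of the distribution (c =
#' occurrence count). The ordering keeps per-length detectability estimates
#' fair: if every occurrence of a length were preceded by short intervals,
#' its apparent detectability would be biased.
#'
#' @param dist An [interval_distribution()].
#' @param time_budget Total stimulation span in minutes; must be at least
#'   twice the maximal supported interval.
#' @param seed Unused (the construction is deterministic); accepted so that
#'   callers can treat all realizers uniformly.
#' @param short_cutoff Lengths `<= short_cutoff` minutes must occur at least
#'   twice (default 12).
#' @return A `pulse_sequence` object; see [pulse_sequence()].
#' @export
realize_pulse_sequence <- function(dist, time_budget, seed = NULL,
                                   short_cutoff = 12) {
  stopifnot(inherits(dist, "interval_distribution"))
  if (time_budget < 2 * max(dist$interval)) {
    stop("time_budget must be at least twice the maximal supported interval",
         call. = FALSE)
  }
  L <- dist$interval
  p <- dist$prob
  short <- L <= short_cutoff & p > 0
  if (sum(2 * L[short]) > time_budget) {
    stop("time budget too small for two occurrences of each short interval",
         call. = FALSE)
  }
  counts <- NULL
  for (npulse in seq.int(floor(time_budget / min(L)) + 2L, 1L)) {
    n <- round(npulse * p)
    n[short] <- pmax(n[short], 2)
    if (sum(n) >= 2 && sum(n * L) <= time_budget) { counts <- n; break }
  }
  if (is.null(counts)) {
    stop("time budget too small to realize the distribution", call. = FALSE)
  }
  ordered <- order_intervals(L, counts, dist)
  pulse_sequence(c(0L, cumsum(ordered)))
}

# Greedy ordering: each occurrence targets the m/(c+1) quantile of `dist`
# as its preceding interval; place the occurrence whose target is nearest
# the last placed interval. Deterministic ties: smaller length, then lower
# occurrence index.
order_intervals <- function(L, counts, dist) {
  cdf <- cumsum(dist$prob)
  qdist <- function(q) dist$interval[which(cdf >= q - 1e-12)[1]]
  occ <- dplyr::bind_rows(purrr::map(seq_along(L), function(i) {
    c <- counts[i]
    if (c == 0) return(NULL)
    tibble::tibble(len = L[i], m = seq_len(c), target = purrr::map_dbl(
      seq_len(c), function(m) qdist(m / (c + 1))))
  }))
  occ <- dplyr::arrange(occ, .data$target, .data$len, .data$m)
  placed <- integer(0)
  remaining <- occ
  # first interval has no predecessor: start from the smallest target
  placed <- remaining$len[1]
  remaining <- remaining[-1, ]
  while (nrow(remaining) > 0) {
    v <- placed[length(placed)]
    d <- abs(remaining$target - v)
    j <- order(d, remaining$len, remaining$m)[1]
    placed <- c(placed, remaining$len[j])
    remaining <- remaining[-j, ]
  }
  as.integer(placed)
}

#' Pulse sequences on a whole-minute clock
#'
#' A pulse sequence records the minutes (0-based) at which light pulses were
#' sent and the total sequence length. `annotate_sequence()` derives, for
#' every minute k, the pulse indicator `x`, the time since the previous
#' pulse `last`, and the length `interval` of the inter-pulse interval
#' containing k. At a pulse minute, `last == interval` (the diagonal
#' property). Minutes at or before the first pulse and after the last pulse
#' are flagged unusable.
#'
#' @param pulse_minutes Sorted non-negative integers.
#' @param n_min Total length in minutes; defaults to the last pulse + 1.
#' @return An object of class `pulse_sequence`.
#' @export
pulse_sequence <- function(pulse_minutes, n_min = NULL) {
  pulse_minutes <- sort(unique(as.integer(pulse_minutes)))
  if (length(pulse_minutes) == 0 || any(pulse_minutes < 0)) {
    stop("pulse minutes must be non-negative integers", call. = FALSE)
  }
  if (is.null(n_min)) n_min <- max(pulse_minutes) + 1L
  stopifnot(n_min > max(pulse_minutes))
  structure(list(pulse_minutes = pulse_minutes, n_min = as.integer(n_min)),
            class = "pulse_sequence")
}

#' @export
print.pulse_sequence <- function(x, ...) {
  cat(sprintf("<pulse_sequence> %d pulses over %d min (first %d, last %d)\n",
              length(x$pulse_minutes), x$n_min, min(x$pulse_minutes),
              max(x$pulse_minutes)))
  invisible(x)
}

#' @rdname pulse_sequence
#' @param seq A `pulse_sequence`.
#' @return `annotate_sequence()`: a tibble with columns `minute`, `x`,
#'   `last`, `interval`, `usable`.
#' @export
annotate_sequence <- function(seq) {
  stopifnot(inherits(seq, "pulse_sequence"))
  if (length(seq$pulse_minutes) < 2) {
    stop("need at least two pulses to annotate", call. = FALSE)
  }
  minute <- seq.int(0L, seq$n_min - 1L)
  pm <- seq$pulse_minutes
  x <- as.integer(minute %in% pm)
  # index of last pulse strictly before each minute
  prev_idx <- findInterval(minute - 1L, pm)
  last <- ifelse(prev_idx >= 1, minute - pm[pmax(prev_idx, 1L)], NA_integer_)
  # interval containing minute k: pulses a < k <= b
  next_idx <- prev_idx + 1L
  nxt <- ifelse(next_idx <= length(pm), pm[pmin(next_idx, length(pm))],
                NA_integer_)
  interval <- nxt - pm[pmax(prev_idx, 1L)]
  interval[prev_idx < 1] <- NA_integer_
  usable <- minute > min(pm) & minute <= max(pm)
  tibble::tibble(minute = minute, x = x,
                 last = as.integer(ifelse(usable, last, NA)),
                 interval = as.integer(ifelse(usable, interval, NA)),
                 usable = usable)
}

#' Empirical interval distribution of a realized pulse sequence
#'
#' Tabulates the gaps between consecutive pulses. The entropy rate of this
#' empirical distribution is the input information rate actually sent when
#' the realized sequence is (conceptually) drawn from its own interval
#' frequencies.
#'
#' @param seq A [pulse_sequence()].
#' @return An [interval_distribution()].
#' @export
empirical_interval_distribution <- function(seq) {
  stopifnot(inherits(seq, "pulse_sequence"))
  gaps <- diff(seq$pulse_minutes)
  if (length(gaps) == 0) stop("need at least two pulses", call. = FALSE)
  tab <- table(gaps)
  interval_distribution(as.integer(names(tab)), as.numeric(tab))
}

#' Stationary joint distribution of (interval, last)
#'
#' Under the per-minute stationary view of the renewal process, a uniformly
#' chosen usable minute falls in an interval of length i with probability
#' proportional to `i * p(i)` and is uniform within it, giving
#' `P(interval = i, last = l) = p(i) / E[L]` for `1 <= l <= i`. The diagonal
#' mass (pulse minutes, `l == i`) sums to the pulse rate `1 / E[L]`.
#'
#' @param protocol A [stimulation_protocol()] or interval distribution.
#' @return A tibble with columns `interval`, `last`, `prob` summing to 1.
#' @export
joint_interval_last <- function(protocol) {
  protocol <- as_stimulation_protocol(protocol)
  d <- protocol$dist
  m <- mean_interval(d)
  tidyr::uncount(
    tibble::tibble(interval = d$interval, prob = d$prob / m),
    weights = .data$interval, .id = "last") |>
    dplyr::mutate(last = as.integer(.data$last)) |>
    dplyr::select("interval", "last", "prob")
}
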