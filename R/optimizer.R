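#' Smoothness penalty on protocol logits
#'
#' The mean of squared second-order differences of the interval
#' log-probabilities, scaled by `alpha`. Because second differences of the
#' logits equal those of the log-probabilities (the softmax normalizer
#' cancels), the penalty is evaluated directly on the logits. It vanishes
#' for any distribution whose log-probability is affine in the interval
#' length (uniform, exponential/geometric) and discourages jagged optimized
#' protocols.
#'
#' @param phi Numeric vector of unnormalized log-probabilities over the
#'   optimization support (>= 3 points).
#' @param alpha Regularization weight (default 0.003).
#' @return A single number (the penalty).
#' @export
regularization_penalty <- function(phi, alpha = 0.003) {
  if (length(phi) < 3) stop("need at least 3 support points", call. = FALSE)
  dd <- diff(phi, differences = 2)
  alpha * mean(dd^2)
}

reg_penalty_grad <- function(phi, alpha = 0.003) {
  n <- length(phi)
  dd <- diff(phi, differences = 2)
  g <- numeric(n)
  # d/dphi_j sum(dd^2): dd_i = phi_{i+2} - 2 phi_{i+1} + phi_i
  g[seq_len(n - 2)] <- g[seq_len(n - 2)] + 2 * dd
  g[seq_len(n - 2) + 1] <- g[seq_len(n - 2) + 1] - 4 * dd
  g[seq_len(n - 2) + 2] <- g[seq_len(n - 2) + 2] + 2 * dd
  alpha * g / (n - 2)
}

softmax <- function(phi) {
  e <- exp(phi - max(phi))
  e / sum(e)
}

# hazard over last = 1..max(support) for a softmax(phi) distribution
phi_hazard <- function(phi, support) {
  p <- numeric(max(support))
  p[support] <- softmax(phi)
  surv <- rev(cumsum(rev(p)))
  ifelse(surv > 0, p / surv, 0)
}

# pointwise bitrate term f (bits) and its derivative w.r.t. the unclipped
# hazard at the point's `last`, given the decoder update u and the clipped
# prior h
point_info_and_dh <- function(u, x, h_raw, clip) {
  h <- pmin(pmax(h_raw, clip), 1 - clip)
  t <- stats::qlogis(h)
  q <- stats::plogis(u + t)
  f <- (ifelse(x == 1, log(q) - log(h), log(1 - q) - log(1 - h))) / log(2)
  dfdh <- (h - q) / (h * (1 - h)) / log(2)
  dfdh[h_raw < clip | h_raw > 1 - clip] <- 0   # clip is flat
  list(f = f, dfdh = dfdh)
}

#' Exact regularized bitrate objective of a candidate protocol
#'
#' Evaluates the expected pointwise surprisal reduction (bits per minute,
#' reported in bit/h) under a candidate interval distribution
#' `softmax(phi)` on `support`: pairs `(interval, last)` are weighted by
#' the candidate's stationary joint distribution, priors are recomputed
#' from the candidate's hazard at the *true* `last`, data for intervals
#' beyond the measured range are imputed ([impute_long_interval()]), and
#' the decoder's update is re-evaluated with the true `log(last)` feature.
#' The smoothness penalty (in bit/h units) is subtracted unless
#' `alpha = 0`.
#'
#' @param phi Logits over `support`.
#' @param model A trained [train_pulse_classifier()] decoder.
#' @param datapoints The evaluation datapoints (typically the transmitting
#'   subpopulation under the experimental protocol).
#' @param support Integer intervals being optimized over (default 5:90).
#' @param alpha Regularization weight.
#' @param prior_clip Hazard clipping constant.
#' @return The objective in bit/h (bitrate minus penalty).
#' @export
protocol_objective <- function(phi, model, datapoints, support = 5:90,
                               alpha = 0.003, prior_clip = 1e-6) {
  stopifnot(length(phi) == length(support))
  prep <- prepare_objective_data(model, datapoints, support)
  exact_objective(phi, prep, alpha, prior_clip)
}

# Precompute, for every (interval, last) pair of the candidate support,
# the mean decoder update over the group that serves the pair, plus the
# pair bookkeeping. u depends on the pair only through log(last), so
# per-pair forwards are batched.
prepare_objective_data <- function(model, datapoints, support) {
  dist0 <- interval_distribution(support, rep(1, length(support)))
  plan <- build_sampling_plan(datapoints, stimulation_protocol(dist0),
                              warn_fallback = FALSE)
  gindex <- group_row_index(datapoints)
  Xall <- feature_matrix(datapoints, model$stats)
  log_last_i <- match("log_last", model$stats$feature)
  mu <- model$stats$mean[log_last_i]
  sdv <- model$stats$sd[log_last_i]

  pair_rows <- lapply(plan$fetch_key, function(k) gindex[[as.character(k)]])
  n_per <- lengths(pair_rows)
  rows <- unlist(pair_rows)
  X <- Xall[rows, , drop = FALSE]
  X[, log_last_i] <- (log(rep(plan$last, n_per)) - mu) / sdv
  u <- mlp_forward(model$weights, X)
  pair_id <- rep(seq_len(nrow(plan)), n_per)
  list(plan = plan, u = u, pair_id = pair_id, support = support)
}

exact_objective <- function(phi, prep, alpha, prior_clip) {
  plan <- prep$plan
  support <- prep$support
  p <- softmax(phi)
  EL <- sum(support * p)
  h <- phi_hazard(phi, support)
  # pair_id is ordered by plan row, so pair attributes broadcast directly
  x_pt <- plan$x[prep$pair_id]
  h_pt <- h[plan$last[prep$pair_id]]
  pi <- point_info_and_dh(prep$u, x_pt, h_pt, prior_clip)
  # mean f per pair, then weight by the candidate joint probability
  fbar <- as.vector(tapply(pi$f, prep$pair_id, mean))
  probs <- p[match(plan$interval, support)] / EL
  60 * sum(probs * fbar) - 60 * regularization_penalty(phi, alpha)
}

#' Importance-weighted gradient of the protocol objective
#'
#' One-sample score-function gradient of the bitrate objective with respect
#' to the protocol logits, derived from the frozen-distribution identity:
#' a batch is drawn under the frozen copy of the protocol, the importance
#' weights are identically 1 at the evaluation point, and their derivative
#' contributes the score term, giving the unbiased estimator
#' `mean(grad f + f * grad log P(interval, last))` minus the penalty
#' gradient. `grad f` flows through the candidate hazard in both the prior
#' term and the posterior's additive prior logit.
#'
#' @param phi Logits over `support` (the frozen copy equals `phi`; it is
#'   refreshed after every step).
#' @param batch A tibble with columns `interval`, `last`, `u` (decoder
#'   update at the true `last`) and `x`, drawn under `softmax(phi)`.
#' @param support Integer support of the optimization.
#' @param alpha Regularization weight.
#' @param prior_clip Hazard clipping constant.
#' @return Gradient vector (bit/h per unit logit), same length as `phi`.
#' @export
importance_gradient <- function(phi, batch, support, alpha = 0.003,
                                prior_clip = 1e-6) {
  n_sup <- length(support)
  p <- softmax(phi)
  EL <- sum(support * p)
  h <- phi_hazard(phi, support)
  maxL <- max(support)

  pi <- point_info_and_dh(batch$u, batch$x, h[batch$last], prior_clip)
  f <- pi$f

  # dh(l)/dphi_m for the l values present: h(l) = p_l / S(l)
  # dp_i/dphi_m = p_i (delta_im - p_m); dS(l)/dphi_m = p_m [L_m >= l] - S(l) p_m
  surv <- rev(cumsum(rev(replace(numeric(maxL), support, p))))
  l_vals <- sort(unique(batch$last))
  # score of the joint: d log P(i, l) / dphi_m = delta_im - p_m - p_m (L_m - EL)/EL
  score_base <- -p - p * (support - EL) / EL       # common part, length n_sup
  grad <- numeric(n_sup)

  # term 1: E[f * score]
  idx_i <- match(batch$interval, support)
  nb <- nrow(batch)
  grad <- grad + sum(f) / nb * score_base
  grad <- grad + as.vector(tapply(f, factor(idx_i, levels = seq_len(n_sup)), sum,
                                  default = 0)) / nb

  # term 2: E[df/dh * dh/dphi]
  in_sup <- batch$last %in% support
  if (any(in_sup)) {
    lpos <- match(batch$last[in_sup], support)     # position of l in support
    wdf <- pi$dfdh[in_sup] / nb
    S_l <- surv[batch$last[in_sup]]
    p_l <- p[lpos]
    # dh(l)/dphi_m = [p_l (delta_lm - p_m) S - p_l (p_m [m>=l] - S p_m)] / S^2
    #             = (p_l/S) delta_lm - (p_l p_m / S^2) [m >= l]
    agg1 <- tapply(wdf * p_l / S_l, factor(lpos, levels = seq_len(n_sup)),
                   sum, default = 0)
    grad <- grad + as.vector(agg1)
    # suffix term: for each m, subtract sum over points with l <= L_m
    coef <- wdf * p_l / S_l^2                       # weight per point
    by_l <- as.vector(tapply(coef, factor(lpos, levels = seq_len(n_sup)),
                             sum, default = 0))
    cum <- cumsum(by_l)                             # sum over l' <= position m
    grad <- grad - p * cum
  }
  60 * grad - 60 * reg_penalty_grad(phi, alpha)
}

#' Optimize the stimulation protocol and estimate channel capacity
#'
#' Gradient ascent on the interval-distribution logits, starting from the
#' experimental protocol (extended with negligible mass over the rest of
#' the support): at each step a minibatch of `(interval, last, data point)`
#' triples is drawn under the frozen current protocol, the
#' importance-weighted gradient is computed, a plain gradient step is
#' taken, and the frozen copy is refreshed. Intervals longer than the
#' measured maximum are served by imputation; intervals shorter than the
#' support minimum (default 5 min) are excluded from the search because
#' cells do not respond to them and no data exist to impute. The reported
#' capacity is the *unregularized* bitrate of the final protocol. Run on
#' the transmitting subpopulation determined under the experimental
#' protocol.
#'
#' @param model A trained [train_pulse_classifier()] decoder.
#' @param datapoints Evaluation datapoints (transmitting cells).
#' @param init_protocol The experimental [stimulation_protocol()] used as
#'   the starting point.
#' @param support Intervals to optimize over (default 5:90 min).
#' @param steps Gradient steps (default 500).
#' @param lr Step size on the logits (default 0.05).
#' @param batch_size Minibatch size (default 1e4).
#' @param alpha Smoothness regularization weight (default 0.003).
#' @param seed Integer seed.
#' @param prior_clip Hazard clipping constant.
#' @return An `optimized_protocol` object: final distribution, capacity in
#'   bit/h, objective trace, and the initial bitrate.
#' @export
optimize_protocol <- function(model, datapoints, init_protocol,
                              support = 5:90, steps = 500, lr = 0.05,
                              batch_size = 10000, alpha = 0.003, seed = 1L,
                              prior_clip = 1e-6) {
  init_protocol <- as_stimulation_protocol(init_protocol)
  d0 <- init_protocol$dist
  p0 <- rep(1e-6, length(support))
  p0[match(d0$interval, support)] <- d0$prob
  phi <- log(p0 / sum(p0))

  prep <- prepare_objective_data(model, datapoints, support)
  plan <- prep$plan
  # group rows by pair for fast batch assembly
  pair_groups <- split(seq_along(prep$pair_id), prep$pair_id)
  set.seed(seed)

  trace <- numeric(steps)
  for (step in seq_len(steps)) {
    p <- softmax(phi)
    probs <- p[match(plan$interval, support)] / sum(support * p)
    counts <- as.vector(stats::rmultinom(1, batch_size, probs))
    take <- which(counts > 0)
    sel <- unlist(lapply(take, function(j) {
      g <- pair_groups[[as.character(j)]]
      g[sample.int(length(g), counts[j], replace = TRUE)]
    }))
    batch <- tibble::tibble(
      interval = rep(plan$interval[take], counts[take]),
      last = rep(plan$last[take], counts[take]),
      x = rep(plan$x[take], counts[take]),
      u = prep$u[sel])
    g <- importance_gradient(phi, batch, support, alpha = alpha,
                             prior_clip = prior_clip)
    if (any(!is.finite(g))) {
      stop("protocol optimization diverged (non-finite gradient) at step ",
           step, call. = FALSE)
    }
    phi <- phi + lr * g
    phi <- phi - max(phi)
    f_new <- point_info_and_dh(batch$u, batch$x,
                               phi_hazard(phi, support)[batch$last],
                               prior_clip)$f
    trace[step] <- 60 * mean(f_new) - 60 * regularization_penalty(phi, alpha)
    if (!is.finite(trace[step])) {
      stop("protocol optimization diverged (non-finite objective) at step ",
           step, call. = FALSE)
    }
  }
  dist_final <- interval_distribution(support, softmax(phi))
  capacity <- exact_objective(phi, prep, alpha = 0, prior_clip = prior_clip)
  b_init <- protocol_objective(log(p0 / sum(p0)), model, datapoints,
                               support = support, alpha = 0,
                               prior_clip = prior_clip)
  structure(
    list(distribution = dist_final, phi = phi, capacity = capacity,
         initial_bitrate = b_init, trace = trace, support = support,
         alpha = alpha),
    class = "optimized_protocol")
}

#' @export
print.optimized_protocol <- function(x, ...) {
  cat(sprintf(
    "<optimized_protocol> support [%d, %d] min | capacity %.2f bit/h (initial %.2f bit/h)\n",
    min(x$support), max(x$support), x$capacity, x$initial_bitrate))
  invisible(x)
}

#' @rdname print.optimized_protocol
#' @param x An `optimized_protocol`.
#' @param ... Unused.
#' @return `tidy()`: the optimized interval distribution as a tibble;
#'   `glance()`: a one-row summary with `capacity`, `initial_bitrate`,
#'   `gain` and `mean_interval`.
#' @export
tidy.optimized_protocol <- function(x, ...) {
  tibble::as_tibble(x$distribution)
}

#' @rdname print.optimized_protocol
#' @export
glance.optimized_protocol <- function(x, ...) {
  tibble::tibble(capacity = x$capacity, initial_bitrate = x$initial_bitrate,
                 gain = x$capacity / x$initial_bitrate - 1,
                 mean_interval = mean_interval(x$distribution),
                 alpha = x$alpha, steps = length(x$trace))
}
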