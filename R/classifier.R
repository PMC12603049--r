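#' The MLP pulse decoder
#'
#' A small multilayer perceptron (hidden sizes 40 and 20, leaky-ReLU
#' activations, negative slope 0.01) maps a standardized feature vector --
#' the trajectory-slice differences, `log(last)`, responsiveness, cell line
#' and the inhibitor triplet -- to a scalar logit-Bayesian update
#' `u_Bayes`. The posterior pulse probability is
#' `logit p = u_Bayes + logit p(X = 1 | last)`, i.e. the network only
#' corrects the protocol prior, which lets one trained decoder generalize
#' across protocols with different priors. The output layer is
#' zero-initialized so that an untrained decoder reproduces the prior
#' exactly (initial bitrate estimate 0).
#'
#' @name pulse_classifier
NULL

new_pulse_classifier <- function(weights, stats, config) {
  structure(list(weights = weights, stats = stats, config = config,
                 loss_trace = numeric(0)),
            class = "pulse_classifier")
}

init_mlp <- function(input_width, hidden = c(40, 20), seed = 1L) {
  set.seed(seed)
  sizes <- c(input_width, hidden, 1L)
  w <- vector("list", length(sizes) - 1)
  for (i in seq_along(w)) {
    fan_in <- sizes[i]
    W <- matrix(stats::rnorm(sizes[i] * sizes[i + 1], 0, sqrt(2 / fan_in)),
                sizes[i], sizes[i + 1])
    if (i == length(w)) W[] <- 0           # start at the prior
    w[[i]] <- list(W = W, b = rep(0, sizes[i + 1]))
  }
  w
}

.lrelu_slope <- 0.01

mlp_forward <- function(weights, X, keep = FALSE) {
  a <- X
  grads_act <- list(); as_ <- list(X)
  for (i in seq_along(weights)) {
    z <- a %*% weights[[i]]$W
    z <- z + rep(weights[[i]]$b, each = nrow(z))
    if (i < length(weights)) {
      g <- .lrelu_slope + (1 - .lrelu_slope) * (z > 0)  # activation slope
      a <- z * g
      if (keep) { grads_act[[i]] <- g; as_[[i + 1]] <- a }
    } else {
      a <- z
    }
  }
  if (keep) list(u = as.vector(a), grads_act = grads_act, as = as_)
  else as.vector(a)
}

# gradient of mean loss w.r.t. weights given dL/du (vector over rows)
mlp_backward <- function(weights, fw, du) {
  grads <- vector("list", length(weights))
  delta <- matrix(du, ncol = 1)
  for (i in rev(seq_along(weights))) {
    if (i < length(weights)) delta <- delta * fw$grads_act[[i]]
    grads[[i]] <- list(W = crossprod(fw$as[[i]], delta),
                       b = colSums(delta))
    if (i > 1) delta <- delta %*% t(weights[[i]]$W)
  }
  grads
}

#' Evaluate the decoder's logit-Bayesian update
#'
#' Standardizes the features of `datapoints` with the statistics stored in
#' the model and runs the MLP forward pass.
#'
#' @param model A trained [train_pulse_classifier()] model.
#' @param datapoints A datapoint tibble (unstandardized features).
#' @return Numeric vector `u_Bayes`, one value per data point.
#' @export
predict_u_bayes <- function(model, datapoints) {
  stopifnot(inherits(model, "pulse_classifier"))
  if (!all(model$stats$feature %in% names(datapoints)) ||
      length(model$stats$feature) != nrow(model$weights[[1]]$W)) {
    stop("feature width does not match the model input width", call. = FALSE)
  }
  X <- feature_matrix(datapoints, model$stats)
  mlp_forward(model$weights, X)
}

feature_matrix <- function(datapoints, stats) {
  feats <- stats$feature
  X <- as.matrix(datapoints[, feats])
  X <- sweep(X, 2, stats$mean, `-`)
  sweep(X, 2, stats$sd, `/`)
}

#' Posterior pulse probability from an update and a prior
#'
#' `sigmoid(u_Bayes + logit(prior))`; with `u = 0` the posterior equals the
#' prior.
#'
#' @param u_bayes Numeric vector of logit updates.
#' @param prior Prior probabilities in (0, 1) (the clipped hazard).
#' @return Posterior probabilities.
#' @export
posterior_probability <- function(u_bayes, prior) {
  if (any(prior <= 0 | prior >= 1)) {
    stop("prior must lie strictly inside (0, 1); clip the hazard first",
         call. = FALSE)
  }
  stats::plogis(u_bayes + stats::qlogis(prior))
}

#' Train the MLP pulse decoder
#'
#' Minimizes the cross-entropy between the pulse indicators and the
#' decoder's posterior over protocol-weighted minibatches
#' ([sample_minibatch()]), using Adam (adaptive-moment stochastic gradient
#' descent). Feature standardization statistics are computed from the full
#' dataset and stored with the model. The loss is computed in nats
#' internally and traced in bits per data point.
#'
#' @param datapoints A datapoint tibble (must contain both pulse and
#'   non-pulse points).
#' @param protocol The assumed [stimulation_protocol()] used for sampling
#'   and priors.
#' @param hidden Hidden layer sizes (default `c(40, 20)`).
#' @param steps Number of gradient steps (default 2000).
#' @param batch_size Minibatch size (default 1e4).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed Integer seed controlling initialization and sampling.
#' @param validation_fraction Fraction of cells held out as a validation
#'   slice for early stopping (default 0.1). Every `eval_every` steps the
#'   cross-entropy on the validation slice is evaluated and the weights
#'   with the best validation loss are kept, so that a decoder trained on
#'   uninformative data falls back to the prior instead of fitting noise.
#'   Set to 0 to disable.
#' @param eval_every Steps between validation evaluations (default 50).
#' @return A `pulse_classifier` object.
#' @export
train_pulse_classifier <- function(datapoints, protocol, hidden = c(40, 20),
                                   steps = 2000, batch_size = 10000,
                                   lr = 1e-3, seed = 1L,
                                   validation_fraction = 0.1,
                                   eval_every = 50) {
  protocol <- as_stimulation_protocol(protocol)
  if (length(unique(datapoints$x)) < 2) {
    stop("dataset must contain both pulse and non-pulse points", call. = FALSE)
  }
  std <- suppressWarnings(standardize_features(datapoints))
  stats_tbl <- std$stats
  feats <- stats_tbl$feature
  weights <- init_mlp(length(feats), hidden, seed = seed)

  # validation slice (whole cells) for early stopping
  set.seed(seed + 2L)
  cells <- unique(datapoints$cell_id)
  n_val <- floor(validation_fraction * length(cells))
  val_rows <- integer(0)
  if (n_val >= 1) {
    val_cells <- sample(cells, n_val)
    val_rows <- which(datapoints$cell_id %in% val_cells)
  }
  train_dp <- if (length(val_rows) > 0) datapoints[-val_rows, ] else datapoints
  if (length(unique(train_dp$x)) < 2) {
    train_dp <- datapoints
    val_rows <- integer(0)
  }

  plan <- build_sampling_plan(train_dp, protocol)
  gindex <- group_row_index(train_dp)
  Xall <- feature_matrix(train_dp, stats_tbl)
  log_last_i <- match("log_last", feats)

  Xval <- NULL
  if (length(val_rows) > 0) {
    Xval <- feature_matrix(datapoints[val_rows, ], stats_tbl)
    val_prior_logit <- stats::qlogis(
      protocol_prior(protocol, datapoints$last[val_rows]))
    val_x <- datapoints$x[val_rows]
  }
  val_loss <- function(w) {
    q <- stats::plogis(mlp_forward(w, Xval) + val_prior_logit)
    -mean(val_x * log(q) + (1 - val_x) * log(1 - q)) / log(2)
  }
  best_weights <- weights
  best_val <- if (!is.null(Xval)) val_loss(weights) else Inf

  # Adam state
  m <- purrr::map(weights, ~ list(W = .x$W * 0, b = .x$b * 0))
  v <- purrr::map(weights, ~ list(W = .x$W * 0, b = .x$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_trace <- numeric(steps)
  set.seed(seed + 1L)

  for (step in seq_len(steps)) {
    counts <- as.vector(stats::rmultinom(1, batch_size, plan$prob))
    take <- which(counts > 0)
    rows <- unlist(lapply(take, function(j) {
      idx <- gindex[[as.character(plan$fetch_key[j])]]
      idx[sample.int(length(idx), counts[j], replace = TRUE)]
    }))
    X <- Xall[rows, , drop = FALSE]
    last_req <- rep(plan$last[take], counts[take])
    x <- rep(plan$x[take], counts[take])
    # requested last enters both the feature and the prior
    X[, log_last_i] <- (log(last_req) - stats_tbl$mean[log_last_i]) /
      stats_tbl$sd[log_last_i]
    prior <- protocol_prior(protocol, last_req)

    fw <- mlp_forward(weights, X, keep = TRUE)
    q <- stats::plogis(fw$u + stats::qlogis(prior))
    loss_trace[step] <- -mean(x * log(q) + (1 - x) * log(1 - q)) / log(2)
    du <- (q - x) / length(x)
    grads <- mlp_backward(weights, fw, du)
    for (i in seq_along(weights)) {
      for (nm in c("W", "b")) {
        g <- grads[[i]][[nm]]
        m[[i]][[nm]] <- b1 * m[[i]][[nm]] + (1 - b1) * g
        v[[i]][[nm]] <- b2 * v[[i]][[nm]] + (1 - b2) * g^2
        mhat <- m[[i]][[nm]] / (1 - b1^step)
        vhat <- v[[i]][[nm]] / (1 - b2^step)
        weights[[i]][[nm]] <- weights[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    if (!is.null(Xval) && (step %% eval_every == 0 || step == steps)) {
      vl <- val_loss(weights)
      if (vl < best_val) { best_val <- vl; best_weights <- weights }
    }
  }
  if (!is.null(Xval)) weights <- best_weights
  model <- new_pulse_classifier(weights, stats_tbl,
                                list(hidden = hidden, steps = steps,
                                     batch_size = batch_size, lr = lr,
                                     seed = seed))
  model$loss_trace <- loss_trace
  model
}

#' @export
print.pulse_classifier <- function(x, ...) {
  np <- sum(purrr::map_int(x$weights, ~ length(.x$W) + length(.x$b)))
  cat(sprintf(
    "<pulse_classifier> input %d -> hidden (%s) -> u_Bayes | %d parameters\n",
    nrow(x$weights[[1]]$W), paste(x$config$hidden, collapse = ", "), np))
  if (length(x$loss_trace) > 0) {
    cat(sprintf("  trained %d steps; final loss %.4f bit/point\n",
                length(x$loss_trace), mean(utils::tail(x$loss_trace, 50))))
  }
  invisible(x)
}

#' Leave-one-replicate-out cross-validation of the decoder
#'
#' For each experimental replicate, trains a decoder on the remaining
#' replicates and evaluates the population bitrate on the full dataset;
#' reports each fold's bitrate and its difference from the all-data model.
#' Small deltas indicate that a single decoder trained on all replicates
#' does not overfit any of them.
#'
#' @inheritParams train_pulse_classifier
#' @param ... Passed to [train_pulse_classifier()].
#' @return A tibble with columns `fold` (held-out replicate), `bitrate`
#'   and `delta` (fold minus all-data bitrate); the all-data model's
#'   bitrate is in attribute `bitrate_all`.
#' @export
loo_crossvalidate <- function(datapoints, protocol, ...) {
  reps <- unique(datapoints$replicate_id)
  if (length(reps) < 2) {
    stop("leave-one-out cross-validation needs at least two replicates",
         call. = FALSE)
  }
  model_all <- train_pulse_classifier(datapoints, protocol, ...)
  b_all <- glance(estimate_bitrate(datapoints, model_all, protocol))$bitrate
  folds <- purrr::map_dfr(reps, function(rep_id) {
    m <- train_pulse_classifier(
      dplyr::filter(datapoints, .data$replicate_id != rep_id), protocol, ...)
    b <- glance(estimate_bitrate(datapoints, m, protocol))$bitrate
    tibble::tibble(fold = rep_id, bitrate = b, delta = b - b_all)
  })
  attr(folds, "bitrate_all") <- b_all
  folds
}

#' Serialize / restore a trained decoder
#'
#' Writes the model as a JSON manifest (versioned) holding the weights,
#' the feature standardization statistics and the training configuration.
#'
#' @param model A `pulse_classifier`.
#' @param path File path (JSON).
#' @return `write_pulse_classifier()` returns `path` invisibly;
#'   `read_pulse_classifier()` returns the model.
#' @export
write_pulse_classifier <- function(model, path) {
  stopifnot(inherits(model, "pulse_classifier"))
  layers <- purrr::map(model$weights, function(l) {
    list(W = as.vector(l$W), dim = dim(l$W), b = l$b)
  })
  payload <- list(
    format = "pulsebit/pulse_classifier", version = 1L,
    layers = layers, stats = model$stats, config = model$config)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pulse_classifier
#' @export
read_pulse_classifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(identical(p$format, "pulsebit/pulse_classifier"))
  weights <- purrr::map(p$layers, function(l) {
    d <- unlist(l$dim)
    list(W = matrix(unlist(l$W), d[1], d[2]), b = as.numeric(unlist(l$b)))
  })
  stats <- tibble::tibble(
    feature = purrr::map_chr(p$stats, "feature"),
    mean = purrr::map_dbl(p$stats, "mean"),
    sd = purrr::map_dbl(p$stats, "sd"))
  new_pulse_classifier(weights, stats, p$config)
}
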