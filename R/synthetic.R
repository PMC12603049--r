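#' Simulation configuration for synthetic KTR track tables
#'
#' The generator emulates the statistical structure of time-lapse kinase
#' translocation reporter (KTR) experiments with pulsatile optogenetic
#' receptor stimulation: a mixture of transmitting and non-transmitting
#' cells, a stereotyped response kernel (calcineurin-mediated dip ~2 min and
#' ERK-mediated peak ~7 min after a pulse), interval-dependent peak
#' amplitude with saturating refractory recovery, autocorrelated noise,
#' slow baseline drift, log-normal receptor expression, an optional
#' spatially clustered phenotype, and a 90-min unstimulated warm-up before
#' the pulse train.
#'
#' Condition covariates modify the phenotype: MEKi abolishes the ERK peak,
#' CALCi abolishes the calcineurin dip, and STE1-like cells respond only
#' under ALKi (with a reduced peak gain and no dip), mirroring EML4-ALK
#' suppression of receptor signaling relieved by ALK inhibition.
#'
#' @param n_cells Cells per replicate.
#' @param n_replicates Number of technical replicates.
#' @param fraction_transmitting Probability that a cell is transmitting.
#' @param cell_line `"BEAS2B"` or `"STE1"`.
#' @param alki_um,meki_um,calci_um Inhibitor concentrations (uM).
#' @param peak_gain,dip_gain Response gains (trajectory units) of
#'   transmitting cells at full recovery.
#' @param ste1_gain_factor Multiplier on `peak_gain` for ALKi-treated
#'   STE1-like cells (their responses are ~5-fold weaker).
#' @param peak_time,dip_time Kernel lobe modes (minutes after pulse).
#' @param peak_shape,dip_shape Gamma shape of each lobe (sets its width).
#' @param recovery_half_time Interval (minutes) at which the peak amplitude
#'   reaches half its asymptote; default 8.5 min (effective refractory time
#'   of the ERK channel is ~8-9 min).
#' @param dip_recovery_half_time Same for the dip channel; small by default
#'   (the calcineurin channel recovers in under 5 min).
#' @param recovery_hill,dip_recovery_hill Hill coefficients of the
#'   saturating recovery `L^h / (L^h + half_time^h)`. The steep default
#'   (3) for the peak channel gives near-absent responses right after a
#'   pulse and a plateau by ~15-20 min; the dip channel recovers almost
#'   immediately (coefficient 1, short half-time).
#' @param noise_sd Stationary s.d. of the AR(1) trajectory noise.
#' @param noise_rho AR(1) autocorrelation per minute.
#' @param meas_sd White measurement noise s.d.
#' @param baseline_drift_sd Total s.d. of the slow random-walk drift over a
#'   track.
#' @param clustering Spatial clustering strength (dimensionless >= 0); 0
#'   gives labels independent of position.
#' @param warmup_min Unstimulated warm-up imaged before the pulse train.
#' @param tail_min Minutes imaged after the final pulse (default 15), so
#'   that trajectory slices of every usable minute are complete.
#' @param background Imaging background intensity (a.u.).
#' @param frame_mean Mean frame intensity (a.u.).
#' @param seed Integer seed; fixed seed gives bit-identical tables.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 200, n_replicates = 1,
                              fraction_transmitting = 0.65,
                              cell_line = c("BEAS2B", "STE1"),
                              alki_um = 0, meki_um = 0, calci_um = 0,
                              peak_gain = 0.45, dip_gain = 0.15,
                              ste1_gain_factor = 0.2,
                              peak_time = 7, dip_time = 2,
                              peak_shape = 8, dip_shape = 3,
                              recovery_half_time = 8.5,
                              dip_recovery_half_time = 0.5,
                              recovery_hill = 3, dip_recovery_hill = 1,
                              noise_sd = 0.05, noise_rho = 0.5,
                              meas_sd = 0.02, baseline_drift_sd = 0.03,
                              clustering = 0, warmup_min = 90, tail_min = 15,
                              background = 10, frame_mean = 100,
                              seed = 1L) {
  cell_line <- match.arg(cell_line)
  stopifnot(n_cells >= 1, n_replicates >= 1,
            fraction_transmitting >= 0, fraction_transmitting <= 1,
            recovery_half_time > 0, noise_sd >= 0, clustering >= 0)
  structure(as.list(environment()), class = "simulation_config")
}

#' Stereotyped single-pulse response kernel
#'
#' The trajectory increment at `t_since_pulse` minutes after a pulse that
#' was preceded by an interval of `preceding_interval` minutes. The kernel
#' is the sum of a negative gamma-shaped lobe with mode `dip_time` (the
#' calcineurin-mediated dip) and a positive lobe with mode `peak_time` (the
#' ERK-mediated peak). Each lobe is scaled by a saturating Hill-type
#' recovery factor `L^h / (L^h + half_time^h)` of the preceding interval
#' L, so the peak amplitude grows with the time since the previous pulse
#' while the dip is nearly interval-independent (its half-time is short).
#'
#' @param t_since_pulse Minutes since the pulse (>= 0); vectorized.
#' @param preceding_interval Interval preceding the pulse (minutes).
#' @param peak_gain,dip_gain Lobe gains; a non-transmitting phenotype has
#'   both equal to 0.
#' @param config A [simulation_config()] supplying kernel shape parameters.
#' @return Numeric vector of trajectory increments.
#' @export
response_kernel <- function(t_since_pulse, preceding_interval,
                            peak_gain, dip_gain,
                            config = simulation_config()) {
  stopifnot(all(t_since_pulse >= 0))
  lobe <- function(t, mode, shape) {
    sc <- mode / (shape - 1)              # gamma mode = (shape-1)*scale
    stats::dgamma(t, shape = shape, scale = sc) /
      stats::dgamma(mode, shape = shape, scale = sc)
  }
  hill <- function(L, tau, h) L^h / (L^h + tau^h)
  rec_peak <- hill(preceding_interval, config$recovery_half_time,
                   config$recovery_hill)
  rec_dip <- hill(preceding_interval, config$dip_recovery_half_time,
                  config$dip_recovery_hill)
  peak_gain * rec_peak * lobe(t_since_pulse, config$peak_time, config$peak_shape) -
    dip_gain * rec_dip * lobe(t_since_pulse, config$dip_time, config$dip_shape)
}

#' Assign spatial positions with optionally clustered phenotypes
#'
#' Cells are placed uniformly in a 1000 x 1000 um field. With
#' `clustering = 0` the transmitting labels are attached to positions in
#' their given order (independent of position). With `clustering > 0` a
#' Gaussian-smoothed random field (kernel s.d. `100 * clustering` um) is
#' evaluated at the positions and the given number of transmitting labels
#' is assigned to the cells above the matching field quantile, producing
#' spatially autocorrelated phenotypes.
#'
#' @param n_cells Number of cells.
#' @param labels Logical vector of transmitting flags, length `n_cells`.
#' @param clustering Dimensionless clustering strength >= 0.
#' @param seed Integer seed.
#' @param field_size Side of the square field (um).
#' @return A tibble with columns `pos_x`, `pos_y`, `transmitting`.
#' @export
assign_positions <- function(n_cells, labels, clustering = 0, seed = 1L,
                             field_size = 1000) {
  stopifnot(length(labels) == n_cells)
  set.seed(seed)
  pos <- tibble::tibble(pos_x = stats::runif(n_cells, 0, field_size),
                        pos_y = stats::runif(n_cells, 0, field_size))
  if (clustering > 0 && n_cells > 1) {
    sigma <- 100 * clustering
    z <- stats::rnorm(n_cells)
    d2 <- as.matrix(stats::dist(cbind(pos$pos_x, pos$pos_y)))^2
    K <- exp(-d2 / (2 * sigma^2))
    field <- as.vector(K %*% z) / rowSums(K)
    # transmitting labels go to the cells with the highest field values
    k <- sum(labels)
    lab <- rank(-field, ties.method = "first") <= k
  } else {
    lab <- as.logical(labels)
  }
  pos$transmitting <- lab
  pos
}

#' Simulate a raw single-cell track table
#'
#' Generates one row per cell-minute with the columns of a raw track table:
#' `replicate_id`, `cell_id`, `minute`, `nuclear_mean`, `frame_mean`,
#' `receptor_mean`, `pos_x`, `pos_y`, `cell_line`, `alki_um`, `meki_um`,
#' `calci_um`, plus the simulation ground truth `transmitting_true`. Minutes
#' run from `-warmup_min` (unstimulated warm-up) to the end of the pulse
#' sequence, on the same clock as `seq`. The latent standardized trajectory
#' is inverted into intensities via
#' `nuclear = background + (frame - background) * exp(-y)`, so
#' [standardize_tracks()] recovers it exactly.
#'
#' @param config A [simulation_config()].
#' @param seq A [pulse_sequence()].
#' @return A tibble (the raw track table).
#' @export
simulate_population <- function(config, seq) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(seq, "pulse_sequence"))
  set.seed(config$seed)
  ann <- annotate_sequence(seq)
  pm <- seq$pulse_minutes
  gaps <- c(NA, diff(pm))            # preceding interval of each pulse
  minutes <- seq.int(-config$warmup_min, seq$n_min - 1L + config$tail_min)
  Tn <- length(minutes)

  # deterministic pulse-response template is phenotype-independent up to
  # gains: precompute per-minute dip/peak components with unit gains
  peak_comp <- numeric(Tn)
  dip_comp <- numeric(Tn)
  cfg1 <- config
  for (i in seq_along(pm)) {
    L <- if (i == 1) 1e6 else gaps[i]   # first pulse: fully recovered
    idx <- which(minutes >= pm[i])
    t_rel <- minutes[idx] - pm[i]
    peak_comp[idx] <- peak_comp[idx] +
      response_kernel(t_rel, L, peak_gain = 1, dip_gain = 0, config = cfg1)
    dip_comp[idx] <- dip_comp[idx] -
      response_kernel(t_rel, L, peak_gain = 0, dip_gain = 1, config = cfg1)
  }

  out <- vector("list", config$n_replicates)
  for (rep_i in seq_len(config$n_replicates)) {
    n <- config$n_cells
    transmitting <- stats::runif(n) < config$fraction_transmitting
    pos <- assign_positions(n, transmitting, config$clustering,
                            seed = config$seed + 104729L * rep_i)
    transmitting <- pos$transmitting

    pg <- ifelse(transmitting, config$peak_gain, 0) *
      exp(stats::rnorm(n, 0, 0.2))
    dg <- ifelse(transmitting, config$dip_gain, 0) *
      exp(stats::rnorm(n, 0, 0.2))
    if (config$cell_line == "STE1") {
      dg[] <- 0                                   # no calcineurin dip in STE1
      pg <- if (config$alki_um > 0) pg * config$ste1_gain_factor else pg * 0
    }
    if (config$meki_um > 0) pg[] <- 0
    if (config$calci_um > 0) dg[] <- 0

    receptor <- stats::rlnorm(n, meanlog = 5, sdlog = 0.3)
    baseline <- stats::rnorm(n, 0.5, 0.1)

    y <- matrix(0, nrow = Tn, ncol = n)
    signal <- outer(peak_comp, pg) - outer(dip_comp, dg)   # dip_comp >= 0
    ar <- matrix(stats::rnorm(Tn * n, 0, config$noise_sd * sqrt(1 - config$noise_rho^2)),
                 Tn, n)
    ar[1, ] <- stats::rnorm(n, 0, config$noise_sd)
    for (t in 2:Tn) ar[t, ] <- config$noise_rho * ar[t - 1, ] + ar[t, ]
    drift <- apply(matrix(stats::rnorm(Tn * n, 0, config$baseline_drift_sd / sqrt(Tn)),
                          Tn, n), 2, cumsum)
    meas <- matrix(stats::rnorm(Tn * n, 0, config$meas_sd), Tn, n)
    y <- sweep(signal + ar + drift + meas, 2, baseline, `+`)

    frame <- config$frame_mean * exp(stats::rnorm(Tn, 0, 0.01))
    nuclear <- config$background + (frame - config$background) * exp(-y)
    receptor_obs <- matrix(stats::rnorm(Tn * n, 0, 0.03), Tn, n)
    receptor_obs <- sweep(exp(receptor_obs), 2, receptor, `*`)

    out[[rep_i]] <- tibble::tibble(
      replicate_id = sprintf("R%02d", rep_i),
      cell_id = rep(sprintf("R%02d_c%04d", rep_i, seq_len(n)), each = Tn),
      minute = rep(minutes, n),
      nuclear_mean = as.vector(nuclear),
      frame_mean = rep(frame, n),
      receptor_mean = as.vector(receptor_obs),
      pos_x = rep(pos$pos_x, each = Tn),
      pos_y = rep(pos$pos_y, each = Tn),
      cell_line = config$cell_line,
      alki_um = config$alki_um,
      meki_um = config$meki_um,
      calci_um = config$calci_um,
      transmitting_true = rep(transmitting, each = Tn))
  }
  dplyr::bind_rows(out)
}
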