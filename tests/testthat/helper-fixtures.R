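# Shared fixtures, built once per test run. Sizes are kept small: the
# fixtures exercise structure and identities; the statistically demanding
# properties run in test-acceptance.R at their stated sizes.

fx_dist <- gamma_interval_distribution()
fx_seq <- realize_pulse_sequence(fx_dist, 1020)
fx_emp <- empirical_interval_distribution(fx_seq)
fx_protocol <- stimulation_protocol(fx_emp)

# short sequence + small mixed population for pipeline-level tests
fx_seq_small <- realize_pulse_sequence(fx_dist, 390)
fx_config <- simulation_config(n_cells = 40, seed = 7)
fx_raw <- simulate_population(fx_config, fx_seq_small)
fx_tracks <- standardize_tracks(fx_raw, background = fx_config$background)
fx_dp <- extract_datapoints(fx_tracks, fx_seq_small)
fx_proto_small <- stimulation_protocol(
  empirical_interval_distribution(fx_seq_small))
fx_model <- train_pulse_classifier(fx_dp, fx_proto_small, steps = 400,
                                   seed = 2)
fx_report <- estimate_bitrate(fx_dp, fx_model, fx_proto_small)

# brute-force sequence entropy of the renewal binary process conditioned on
# a pulse at time 0 (independent oracle for the chain-rule identity)
brute_force_sequence_entropy <- function(dist, N) {
  h <- hazard_from_distribution(dist)$hazard
  maxL <- length(h)
  rec <- function(k, last, logp) {
    if (k > N) return(2^logp * (-logp))
    hz <- if (last >= maxL) 1 else h[last]
    tot <- 0
    if (hz > 0) tot <- tot + rec(k + 1, 1L, logp + log2(hz))
    if (hz < 1) tot <- tot + rec(k + 1, last + 1L, logp + log2(1 - hz))
    tot
  }
  rec(1L, 1L, 0)
}
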