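# pulsebit

How many bits per hour does a signaling pathway carry from a receptor to
its downstream effectors? `pulsebit` answers this question for pulsatile
receptor stimulation read out by kinase translocation reporters (KTRs) in
single cells. It is written for quantitative cell biologists who stimulate
cells optogenetically with pseudorandom light-pulse trains (e.g.
optoFGFR + ERK-KTR, imaged once per minute) and want a principled,
decoder-based estimate of the information transmission rate (*bitrate*) of
the pathway, per cell and per population, together with an in-silico
optimization of the stimulation protocol (channel capacity).

## The estimator

Stimulation is interval-encoded: the pulse train `X = X_1 … X_N`
(`X_k = 1` if a pulse was sent at minute k) is a renewal process whose
inter-pulse intervals L are i.i.d. from a distribution p(L). The
information sent per minute is the entropy rate H(L)/E[L]; in bit/h,

    input rate = 60 · H(L) / E[L],

maximal (60 bit/h) for per-minute Bernoulli(1/2) pulses. The information
*received* is bounded from below via a neural decoder. For every cell j
and minute k a small MLP (hidden layers 40 and 20, leaky ReLU) maps the
trajectory-slice differences Δy, the time since the previous pulse
(`log last_k`), a responsiveness score s, and condition covariates to a
logit-Bayesian update u, so that

    logit p_θ(X_k = 1 | …) = u + logit p(X_k = 1 | last_k),

where the second term is the protocol's hazard (the prior). Training
minimizes the cross-entropy of these posteriors, an upper bound on
H(X | Y); subtracting it from the prior surprisal gives a lower bound on
the mutual information rate:

    b = −(1/D) Σ_{j,k} [ log p(x_k | last_k) − log p_θ(x_k | …) ]   (bit/min → ×60 bit/h)

Per-cell bitrates b_j (which can be negative for cells the shared decoder
systematically misreads) average, weighted by track length w_j, exactly to
the population bitrate. Cells are split into transmitting and
non-transmitting subpopulations by the longest low-bitrate prefix that
averages below zero. A protocol optimizer maximizes the bitrate estimate
over interval distributions (support 5–90 min) by importance-weighted
stochastic gradient ascent on the interval logits, imputing unmeasured
long intervals from the longest measured one and penalizing rough
protocols; the unregularized bitrate of the optimized protocol estimates
the channel capacity.

A synthetic track generator (`simulate_population()`) emulates the
experiments — dip (≈2 min) and peak (≈7 min) response lobes,
interval-dependent amplitude with refractory recovery, transmitting /
non-transmitting mixtures, inhibitor and cell-line effects, autocorrelated
noise, clustered spatial phenotypes — so the entire pipeline is testable
without microscopy data.

## Worked example

```r
library(pulsebit)
library(dplyr)

design <- gamma_interval_distribution(shape = 4, scale = 5,
                                      support_min = 5, support_max = 35)
seq    <- realize_pulse_sequence(design, time_budget = 17 * 60)
seq
#> <pulse_sequence> 56 pulses over 981 min (first 0, last 980)
emp    <- empirical_interval_distribution(seq)
emp
#> <interval_distribution> 31 lengths on [5, 35] min | mean 17.82 min | 4.87 bit/pulse | 16.39 bit/h

proto  <- stimulation_protocol(emp)
cfg    <- simulation_config(n_cells = 60, seed = 7)
raw    <- simulate_population(cfg, seq)
tracks <- standardize_tracks(raw, background = cfg$background)
dp     <- extract_datapoints(tracks, seq)
model  <- train_pulse_classifier(dp, proto, steps = 400, seed = 2)
report <- estimate_bitrate(dp, model, proto)
report
#> <bitrate_report> 60 cells | population 8.46 bit/h (SE 0.85) | transmitting 63% |
#>   transmitting-subpop 13.40 bit/h | input 16.39 bit/h
glance(report)
```

Reading the output: the realized 17-hour pulse train sends 16.39 bit/h;
the simulated population (65% transmitting cells by construction)
transmits 8.46 bit/h on average; the transmitting subpopulation alone
reaches 13.4 bit/h. `tidy(report)` gives the per-cell bitrates,
`autoplot(report)` the bitrate histogram with the transmitting threshold,
and

```r
cells <- tidy(report)
dpt   <- semi_join(dp, filter(cells, transmitting),
                   by = c("replicate_id", "cell_id"))
opt   <- optimize_protocol(model, dpt, proto, steps = 200, seed = 4)
```

estimates the channel capacity `opt$capacity` with the optimized interval
distribution `tidy(opt)`.

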