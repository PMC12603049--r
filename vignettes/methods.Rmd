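---
title: "Estimating information transmission rates of pulsatile signaling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating information transmission rates of pulsatile signaling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `pulsebit`, the assumptions they
make, the tunable parameters, and the numerical and design choices that a
user or reviewer should know about. Code chunks illustrate usage and are
not evaluated at build time; every empirical number quoted in the package
is produced by the test suite or by `scripts/acceptance.R`.

## The channel model

We treat a signaling pathway as a communication channel. The input is a
pulse train on a whole-minute clock (matching a 1-min imaging cadence): a
pulse occupies exactly one minute bin, and the gaps between consecutive
pulses are drawn independently from an interval distribution p(L). This
*interval encoding* makes the pulse train a renewal process. Two
consequences are used throughout:

* the probability of a pulse at minute k given the whole stimulation
  history depends only on the time since the previous pulse (`last_k`),
  through the hazard h(l) = p(L = l) / P(L >= l);
* the input entropy rate is H(L)/E[L] bits per minute, i.e.
  `entropy_rate()` = 60 H(L)/E[L] bit/h. A per-minute Bernoulli(1/2)
  train is the 1-minute-resolution maximum, 60 bit/h. The test suite
  checks the chain-rule identity against brute-force enumeration of all
  binary sequences on a 14-minute horizon for small protocols.

The output is the cell's standardized reporter trajectory
y = −log[(nuclear − background)/(frame − background)], one value per
minute. Background is a per-replicate scalar supplied by the user (image-
level background estimation is out of scope); frame normalization uses the
provided frame-mean column. The map is exactly invertible given background
and frame, which the tests exploit for round-trip checks.

## The decoder lower bound

The mutual information rate between input and output is bounded from below
by replacing the intractable posterior p(X_k | history, Y) with a trained
approximation p_θ and averaging surprisal reductions over all usable
cell-minutes. The bound has two practical consequences. First, it is
*safe*: a decoder can only under-estimate the true rate (up to estimator
noise), never systematically invent information — the suite verifies this
on pulse-independent synthetic data. Second, it is *tight only as far as
the decoder is good*: all rates should be read as "at least this much".

The decoder sees, per minute k: the r = 6 within-slice differences of
y_{k..k+6} (differences remove each cell's reporter-expression offset),
log(last_k) (natural log), a per-cell responsiveness score
s = population-sd of 7-minute changes (computed over all timepoints, so it
carries no pulse-timing information), a 0/1 cell-line indicator and the
three inhibitor concentrations. Dip-only and peak-only decoders use slices
y_{k..k+2} and y_{k+6..k+12} instead. Features are standardized to zero
mean and unit sd with dataset-wide statistics stored in the model and
re-applied verbatim at inference; zero-variance features (constant
covariates in single-condition datasets) are scaled by 1 with a warning.

The MLP (hidden sizes 40 and 20, leaky ReLU slope 0.01) outputs a single
logit update u added to the prior logit of the protocol hazard. The
additive-prior architecture is what allows one trained decoder to be
evaluated under different assumed protocols: only the prior term changes.
The hazard is exactly 1 at the maximal supported interval and 0 below the
support minimum, so priors are clipped into [1e-6, 1 − 1e-6] before logit
transforms to keep them finite.

### Training

Minibatches (10^4 points) are drawn by first sampling (interval, last)
pairs from the stationary joint distribution of the assumed protocol —
P(i, l) = p(i)/E[L] for 1 ≤ l ≤ i — and then resampling data points with
replacement from the matching groups; pairs without data borrow from the
Manhattan-nearest non-empty group (with a warning). The loss is the
cross-entropy of the posterior at the *requested* pair's pulse indicator,
computed in nats and reported in bits. The optimizer is Adam with learning
rate 1e-3 and 2000 steps by default; the architecture is small enough
that training takes seconds to a couple of minutes on one CPU.
Initialization uses fan-in-scaled Gaussian weights with a zero output
layer, so an untrained decoder reproduces the prior exactly and the
initial bitrate estimate is exactly 0 — a clean anchor for the
lower-bound property.

By default 10% of cells are held out as a validation slice and the
weights with the best validation cross-entropy (checked every 50 steps)
are returned. This early stopping matters for honesty of the null: on
uninformative data a decoder trained to completion drifts into noise
features, and its held-out posteriors are slightly *worse* than the prior
(a small negative bitrate bias that becomes statistically visible at
thousands of cells). Validation selection returns the prior model in that
regime and the converged model when there is signal.

### Evaluation

Bitrates are evaluated deterministically: every usable data point exactly
once, no resampling (sampling weights apply only to training). The
per-cell bitrate is the mean surprisal reduction over the cell's minutes
times 60; the population bitrate is the track-length-weighted mean of
per-cell bitrates and is *identically* the pooled average (checked to
1e-12). The standard error reported in `glance()` is the weighted
between-cell SE, treating cells as independent.

Cells are split by sorting per-cell bitrates and declaring
non-transmitting the longest prefix whose weighted mean is strictly
negative; the transmitting fraction is the weighted complement share. The
split can be computed pooled across replicates (for histograms) or per
replicate (for fraction and subpopulation summaries); both modes are
exposed because replicate-level factors shift whole histograms.

Per-cell evaluation reuses the decoder trained on all cells without
retraining. This mirrors how a single shared decoder is meant to be used,
but it means a cell's own data influenced the decoder; the early-stopping
validation slice and the held-out evaluations in the test suite bound the
resulting optimism.

## Protocol optimization and capacity

The bitrate estimate is maximized over interval distributions on 5–90 min,
parameterized as softmax of logits (86 free parameters; ties at equal mass
resolve toward shorter intervals only through initialization, as softmax
is smooth). Gradients use the frozen-distribution importance-weight
identity: batches are drawn under a frozen copy of the current protocol,
the importance weights are identically 1 at the evaluation point, and
their derivative contributes the score term. The estimator is unbiased;
the suite checks it against central finite differences of the exact
(enumerated) objective on a 3-interval toy at 10^6 samples within 2%.
Plain gradient ascent with step 0.05 on the logits for 500 steps is the
default; the frozen copy is refreshed after every step.

Data points for intervals longer than the measured maximum (35 min) are
imputed from the 35-min interval: time since the pulse is preserved below
10 min, time to the next pulse is preserved below 10 min, and the interior
is stretched linearly; the map is continuous across branches (checked by
enumeration over intervals 36–90) and the fractional imputed `last*` is
rounded to the nearest measured minute for group lookup. The decoder
always receives the *true* last, both as a feature and in the prior, so
imputation never touches the prior term. Intervals below 5 min are
excluded from the search space: cells do not respond to them, and there is
no data from which to impute a response.

Optimization is performed on the transmitting subpopulation determined
under the experimental protocol (the split itself depends on the protocol,
so it is frozen at the experimental one). A smoothness penalty — α times
the mean squared second difference of the interval log-probabilities, α =
0.003 — discourages jagged protocols that chase per-interval estimator
noise; second differences of the logits equal those of the
log-probabilities, so the penalty is evaluated on the logits directly. The
reported capacity is the *unregularized* bitrate of the final protocol
(the penalty is an optimization device, not part of the quantity being
estimated), and the suite checks that α = 0.003 versus α = 0 changes the
capacity by under 5%.

## The synthetic generator

`simulate_population()` produces raw track tables with the statistical
structure the analysis assumes:

* **Response kernel.** Gamma-shaped lobes (timings are known, functional
  forms are a modeling choice): a negative dip with mode 2 min and a
  positive peak with mode 7 min. Each lobe is scaled by a Hill-type
  recovery L^h/(L^h + τ^h) of the preceding interval. The peak channel
  defaults to τ = 8.5 min, h = 3 — responses right after a pulse are
  nearly absent, recover to half at 8.5 min and plateau by ~15–20 min —
  while the dip channel (τ = 0.5 min, h = 1) is effectively
  interval-independent. The steep Hill form was chosen over a Michaelis
  form because a gradual recovery leaves short-interval pulses clearly
  detectable and no refractory half-crossing exists to measure.
* **Phenotype mixture.** Cells are transmitting with a configurable
  probability (default 0.65); non-transmitting cells have zero gains.
  Gains are log-normally dispersed between cells. MEKi zeroes the peak,
  CALCi zeroes the dip, STE1-like cells respond only under ALKi and then
  at a 5-fold reduced gain with no dip.
* **Noise.** AR(1) per-minute noise (ρ = 0.5, stationary sd 0.05) plus
  white measurement noise (sd 0.02) plus a slow random-walk baseline
  drift (total sd 0.03). Real single-cell noise magnitudes are not
  published; these defaults are chosen so that transmitting and
  non-transmitting subpopulations are clearly separated at the default
  gain, and they are stated once here and not tuned per analysis.
* **Geometry.** Uniform positions in a 1 mm square; with clustering > 0,
  transmitting labels are assigned by thresholding a Gaussian-smoothed
  random field at the quantile matching the transmitting fraction.
* **Bookkeeping.** A 90-min unstimulated warm-up precedes the pulse train
  and 15 min of imaging follow the final pulse, so every usable minute has
  a complete trajectory slice; intensities invert the standardization map
  exactly, and receptor expression is log-normal per cell.

What the generator does *not* emulate: mechanistic pathway dynamics
(no ODEs), cell division, tracking errors and gaps, photobleaching,
heavy-tailed or state-switching noise, and time-varying responsiveness.
Passing tests therefore demonstrate correctness of the estimator under the
assumed statistical structure, not robustness to every artifact of real
microscopy data.

## Stimulation-sequence realization

`realize_pulse_sequence()` converts an interval distribution into a
concrete pulse sequence under a time budget: integer interval counts
proportional to the distribution, with every length at or below 12 min
(a configurable "short" cutoff) forced to occur at least twice, and a
greedy ordering in which the m-th occurrence of a repeated length is
preceded by an interval near the m/(c+1) quantile of the distribution.
This keeps per-length detectability estimates fair — a pulse following a
short interval responds more weakly if the previous interval was also
short. The construction is deterministic. Under the default design
(Gamma shape 4, scale 5 min, support 5–35 min, 17-h budget) the realized
sequence's empirical interval distribution carries 16.39 bit/h — higher
than the 15.84 bit/h of the idealized discretized Gamma, because the
short-interval repetition rule shifts mass toward short intervals.

## Numerical choices and degenerate inputs

* Logs: natural log for the `log(last)` feature and internal losses;
  base 2 at all reporting boundaries; bit/h = bits-per-minute × 60.
* Prior clipping 1e-6; clipped hazards have zero derivative in the
  optimizer (the clip is flat).
* Population-sd convention (denominator n, weighted) for the receptor
  preselection; both the mean and sd are track-length weighted. The
  responsiveness score of a track with a single valid 7-min difference is
  0 by the same convention.
* Track-length filter boundary is inclusive (a 180-min track is kept).
* Receptor preselection of a single-track replicate keeps the track with
  a warning; a zero-variance replicate keeps everything.
* Responsiveness is computed on the tracks as given, i.e. after whatever
  filtering has been applied upstream; the score depends only on the
  cell's own trajectory, so filter order affects nothing but which cells
  exist.
* Empty sampling groups borrow from the Manhattan-nearest non-empty
  (interval, last) group, with a warning.
* Ties in nearest-neighbor ranking are broken by cell order, making the
  spatial analysis deterministic; positions are taken at track midpoint
  time when pooling frames.
* The effective refractory time interpolates the first crossing of half
  the asymptote, with the asymptote estimated as the mean over the top
  quartile of tested intervals (a plateau estimator has to be chosen;
  this one is robust to a noisy largest interval). A curve already above
  half-asymptote at the smallest tested interval reports "below support";
  a non-positive asymptote reports "undefined".

## Problem sizes used by the test suite

The statistically demanding properties run at the sizes the analysis is
designed for: the null/bound property on 2000 cells over an 8-h sequence
with a held-out half; transmitting-fraction recovery on 500 cells over the
17-h design sequence; the noiseless-channel consistency check on 50 cells
(where the estimate reaches > 95% of the 16.39 bit/h input rate); gradient
unbiasedness at 10^6 toy samples; protocol optimization on 50
interval-insensitive cells. Unit tests use smaller fixtures (40 cells,
6.5-h sequence, 400 training steps) that exercise structure and exact
identities rather than statistical power.

## Known limitations

* The bound is only as tight as the decoder; a richer decoder could
  reveal more information (though for this problem larger architectures
  have not helped).
* Single-cell bitrates reuse a decoder trained on all cells; negative
  values are a feature of the estimator, not of physics.
* The capacity search space excludes sub-5-min intervals; for channels
  with very short refractory times (the dip channel) the reported
  capacity is therefore conservative.
* The sequence realizer's greedy ordering approximates, not solves, the
  quantile-matching assignment; predecessors of repeated lengths spread
  across the distribution but need not hit the quantiles exactly.
* Confidence intervals are between-cell SEs (or bootstrap over cells);
  nested cross-validation is not implemented.
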