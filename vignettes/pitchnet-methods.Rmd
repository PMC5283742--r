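---
title: "Methods: passing networks, positional regularity, and the inference layer"
author: "pitchnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: passing networks, positional regularity, and the inference layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
conventions behind each stage, the tunable parameters and why their defaults
are what they are, what the synthetic-match generator does and does not
emulate, and the numerical choices that matter when results are compared
across implementations.

## The analysis in one paragraph

For each team of a match, successful passes among the 10 outfield players
(goalkeepers are excluded from every stage) are aggregated into a directed
weighted adjacency; geodesic closeness and betweenness centralities are
computed from it. In parallel, the tracking stream yields the 45 teammate
dyad distance series, each summarised by Approximate Entropy (ApEn); a
BIC-selected Gaussian mixture classifies dyads into higher / medium / lower
positional regularity, and a joint Voronoi tessellation over both teams
gives each player's dominant region (mean area, CV). The statistical layer
then compares teams (standardized differences, percent differences,
magnitude-based inference) and correlates pass counts with dyad regularity.

## Passing networks

**Edge lengths.** The adjacency stores raw pass counts. Shortest paths need
a count-to-length map, and two conventions are provided because the choice
is genuinely open in this literature:

- `reciprocal` (default): `length(v, w) = 1 / A[v, w]`, so a frequently
  used connection is geodesically short. Multiplying all counts by `k`
  multiplies every closeness by `k` and leaves betweenness invariant — a
  property the tests assert.
- `hop`: every existing edge has length 1 (unweighted replication).

Both conventions are reported in the output metadata; analyses that compare
across matches should fix one.

**Path census.** Dijkstra from each source with shortest-path counting;
the per-intermediate counts use the standard decomposition
`σ_st(v) = σ_sv · σ_vt` whenever `dist(s, v) + dist(v, t) = dist(s, t)`.
With reciprocal lengths, tied path lengths arise from sums of unit
fractions, so equality is tested with a *relative* tolerance of `1e-12`;
without it, floating-point noise splits genuinely tied geodesics and
corrupts the betweenness denominators. The implementation is validated
against an exhaustive simple-path enumeration oracle on hundreds of small
random digraphs (both conventions) and cross-checked against igraph.

**Unreachable targets.** Closeness sums distances over *reachable* targets
only and reports `reachable_count` alongside; summing infinite farness
would zero out scores on weakly connected match networks, and silently
ignoring reachability would make scores incomparable. A player reaching no
one scores 0. Betweenness credits no endpoint pairs (`s ≠ v ≠ t`).

## Approximate Entropy of dyad distances

The classical statistic: `ApEn = Φ^m(r) − Φ^{m+1}(r)` where
`Φ^m(r) = (N−m+1)^{-1} Σ_i ln C_i^m(r)` and `C_i^m(r)` is the fraction of
templates of length `m` within max-norm distance `r` of template `i`,
self-matches included. Defaults `m = 2`, `r = 0.2 · SD(series)` follow the
convention of the movement-science literature; both are echoed in every
output because ApEn values are comparable only within one parameterisation.
Tying `r` to the series SD makes the statistic invariant under affine
rescaling (asserted as a property test). Values for match-scale dyad
distance series typically fall between 0 and 2 in these units, but that is
an empirical range, not a bound, and is not enforced.

Conventions that matter for reproduction:

- missing samples are removed, not interpolated, before computation;
  `n_valid` is reported and dyads under 100 valid samples are flagged
  low-confidence;
- the series is analysed per period and combined as a sample-size-weighted
  mean, avoiding the artificial discontinuity at half-time; whole-match
  concatenation is available (`per_period = FALSE`);
- a constant series returns exactly 0 with a `constant` flag; fewer than
  `m + 2` samples is an error;
- long series may be decimated to a cap per period (uniform stride) to
  bound the quadratic template search; the cap used is recorded in the
  report provenance.

The implementation is a row-blocked vectorisation of the definition and is
tested to `1e-10` against a direct template-by-template oracle.

## Dominant regions

Each processed frame is tessellated jointly over the 20 outfield players of
both teams — a dominant region is only meaningful against the opposition —
and clipped to the pitch rectangle. Cells are computed exactly as half-plane
intersections (Sutherland–Hodgman clipping of the pitch rectangle by the 19
perpendicular bisectors), so per-frame areas sum to the pitch area to
machine precision; the tests assert conservation at `1e-6` relative and
agreement with a nearest-site raster oracle. Degenerate coincident positions
receive a deterministic `1e-6` m perturbation keyed to point index, so the
tessellation is always defined and reproducible. Frames are processed every
second by default (`stride_s = 1`); the per-player summary uses the sample
SD for the coefficient of variation (`100 · SD / mean`).

## Regularity classes

The 45 dyad ApEn values of a team are classified with a one-dimensional
Gaussian mixture: EM for each candidate `k` in 1–5 (a deterministic
quantile-based start plus 20 random restarts, best likelihood kept), `k`
selected by BIC (`2 logL − p log n`, `p = 3k − 1`), components mapped to
labels by ascending mean — lowest ApEn = "higher" regularity. Component
variances are floored at 1% of the data variance: without a floor, EM
collapses onto near-singleton spikes whose likelihood diverges, and BIC then
over-selects `k`. The floor means no component can be narrower than a tenth
of the overall spread, which is appropriate for a 45-point summary
statistic. `k` is *selected*, not forced; `force_k = 3` reproduces a
fixed three-class scheme when desired. All-identical inputs collapse to a
single class with a warning. Recovery of a planted three-component mixture
(means 0.2 / 0.6 / 1.0, SD 0.02, 15 points each) is asserted over 50 seeds.

## The statistical layer

- **Standardized differences**: `d = (mean_B − mean_A) / s_pooled`; the 90%
  limits use the large-sample normal approximation with
  `SE = sqrt(1/n_A + 1/n_B + d²/(2(n_A+n_B)))` rather than noncentral-t
  inversion — at `n = 10` per team the difference is far below the
  reporting resolution, and the method is recorded in the result metadata.
- **Percent differences** for count-type measures are analysed on the
  natural-log scale (back-transformed mean ratio, pooled-variance t
  interval); a raw-difference mode exists for data with zeros. Within-match
  variability for single-match totals comes from splitting the match into
  six equal segments by default and treating per-segment counts as
  replicates; the segmentation is configurable and recorded, since a
  single match provides no other variance basis.
- **Magnitude-based inference**: probabilities that the true effect exceeds
  +SWD, lies within ±SWD, or is below −SWD from the t (or normal) sampling
  distribution of the estimate; SWD defaults to 0.2 standardized units.
  The most probable class is labelled by its probability band (25–75%
  possible, 75–95% likely, 95–99% very likely, >99% most likely); a value
  exactly at a band or magnitude threshold takes the lower band's label,
  implemented with `1e-9` slack so the convention is stable under floating
  point. When the 90% interval spans both +SWD and −SWD the effect is
  "unclear" regardless of the probabilities. Note that the three class
  probabilities always sum to 1 and their maximum is at least 1/3, so the
  "possible" band is always reachable; however, a diffuse estimate whose
  maximum probability is in the "possible" range usually also has an
  interval spanning both substantial signs and is then reported unclear —
  the band tests therefore exercise the boundaries at a standard error
  narrow enough for a clear interval.
- **Correlations**: Pearson `r` over complete pairs with Fisher-z 90%
  limits (`tanh(atanh(r) ± 1.645/√(n−3))`); `|r| = 1` yields a degenerate
  interval at `r`. The directed pass-count mode pairs both directions of a
  dyad with the same ApEn value (90 pairs); the undirected mode sums the
  two counts (45 pairs). A zero-variance ApEn vector makes the correlation
  undefined; the pipeline surfaces this as an "unclear" result with a
  degeneracy flag rather than an error.
- **Efficacy**: `goals × 100 / shots`, one decimal.

## The synthetic-match generator

The generator's job is to produce matches with the statistical structure the
analysis assumes, under controllable conditions — not to simulate football.

**Movement.** Each player follows a discretised mean-reverting (AR(1) /
Ornstein–Uhlenbeck) process around a moving target
`anchor + gain · (ball − pitch centre)`, with stationary noise SD
`noise_sd_m` (default 1 m, the single regularity knob), relaxation time 8 s,
at 5 Hz on a 106 × 65 m pitch, in a 1-4-3-3 formation, two 25-minute periods
by default. The ball is an independent *smooth* stochastic path — an
integrated OU velocity process rescaled to a 20 × 12 m amplitude around the
pitch centre. Two modelling choices are load-bearing:

- the ball must be smooth (integrated, not plain OU): the regular,
  predictable component of dyad distances comes from ball-driven collective
  motion, and a jittery ball would be indistinguishable from positional
  noise in the ApEn sense;
- ball-following gains are graded by role (defenders ~0.4–0.7, midfielders
  ~0.9–1.1, forwards ~1.2–1.5 of the base coupling): with identical gains
  the ball term is common-mode and cancels exactly in every teammate
  distance, leaving nothing but noise — dyad regularity would then be
  insensitive to the noise knob. With graded gains, mean dyad ApEn is
  strictly increasing in `noise_sd_m`, asserted over seeds in the tests.

**Passes.** `simulate_passes` draws a Markov chain of receivers from a
row-stochastic 10 × 10 transition matrix (uniform by default; `hub_bias`
redirects flow through one role so chains alternate hub–others). Event
times are uniform over the match — ApEn and Voronoi do not consume pass
times, so timing realism buys nothing. The default 450 successful passes
per team sits in the typical range for a youth match.

**Planted pass–regularity coupling.** `make_match_fixture` draws per-player
noise SDs log-uniformly over 0.4–2.5× the base value, simulates the
trajectories, computes the realised dyad ApEn, and builds per-dyad pass
propensities as `ρ′ · z(ApEn) + sqrt(1 − ρ′²) · ε`; directed counts are
multinomial in these propensities (both directions share the dyad
propensity). Because multinomial sampling attenuates the realised
count–ApEn correlation by the predictable factor
`sd(μ)/sqrt(sd(μ)² + mean(μ))`, the latent coupling `ρ′` is strengthened by
its inverse (capped at 0.99), so the *realised* correlation matches the
requested `planted_rho`. The coupling is exact in expectation only; near
`ρ = −1` the cap makes the target unattainable by construction. Shot events
get uniform times with `goals ≤ shots` enforced.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: opponent interaction and pressing, ball-possession
physics, set pieces, substitutions and fatigue drift, measurement artefacts
of GPS units (the io layer's gap handling and low-pass filter exist for
real streams but the generator produces clean grids), and any tactical
semantics of the formation beyond anchor geometry.

## Input handling

Geodetic streams are projected with a local equirectangular map
(`x = Δlon · cos(lat0) · 111320`, `y = Δlat · 110540` m/deg, then rotated
into the pitch frame). These fixed per-degree constants are accurate to
about 1% against great-circle distances at pitch scale for |lat| ≤ 60°
(the meridian scale constant sits ~0.7% below the spherical value); for
the sub-pitch displacements this pipeline consumes, that error is far below
GPS noise. Resampling interpolates linearly onto the uniform clock but
never bridges gaps longer than `max_gap_s` (default 2 s) — those grid
points are marked missing and excluded from ApEn. An optional zero-phase
low-pass (two-pass 5-sample moving average) smooths positions after
resampling. Pass logs keep only successful events, reject self-passes with
a warning, drop goalkeeper rows with a logged count, and refuse unknown
player ids.

## Problem sizes used by the tests and the acceptance script

Simulated matches in the test-suite use 1–5 minute periods at 5 Hz — the
pipeline is length-invariant, and these sizes keep the quadratic ApEn stage
and the 100-match recovery experiments at desk scale. The acceptance script
analyses one reference match (two 1-minute periods, 450 passes per team,
planted ρ = −0.4), then measures recovery over 100 matches, hub-topology
betweenness over 50 seeds, cluster recovery over 50 seeds, the
noise-vs-sine ApEn ordering over 20 seeds, and Voronoi conservation over
100 random frames.

## Known limitations

- ApEn is sampling-rate dependent; values from streams resampled at other
  rates are not comparable to 5 Hz values.
- The percent-difference variance basis (six match segments) is a
  documented stand-in for replicate matches, not a reconstruction of any
  particular reporting pipeline.
- The regularity mixture assumes approximate normality within classes; with
  45 points the BIC choice between k = 2 and k = 3 can be data-sensitive,
  which is why `force_k` exists.
- The betweenness tie-handling tolerance (`1e-12` relative) is appropriate
  for reciprocal-count lengths; exotic user-supplied length matrices with
  near-ties at other scales may need a different tolerance.
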