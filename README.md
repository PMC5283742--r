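# pitchnet

Coupled notational and spatio-temporal analysis of team sports performance.

Match analysis in football (and other invasion team sports) has traditionally
split into two camps: *notational* analysis, which counts discrete events
such as passes and shots, and *positional* analysis, which works on the
continuous player-tracking stream. `pitchnet` couples the two for a single
match: it characterises each team's passing interactions as a directed
weighted network, quantifies how regularly every pair of teammates co-moves,
carves the pitch into per-player dominant regions, and relates the two views
statistically — so that questions like *"do teammates who pass more to each
other also hold more regular spatial relations?"* become computable.

## What it computes

**Passing network.** Successful passes between the 10 outfield players of a
team (goalkeepers are excluded throughout) define a directed weighted
adjacency: `A[v, w]` = passes from `v` to `w` — 45 unordered dyads, 90
directed dyads. Geodesic distances over the network (by default edge length
`1/A[v, w]`, so frequent pairs are "close"; an unweighted hop convention is
also available) give two per-player centralities:

- closeness: `C(v) = 1 / Σ_w dist(v, w)` over reachable targets — how easily
  a player is reached as a passing target;
- betweenness: `B(v) = Σ_{s≠v} Σ_{t≠v} σ_st(v) / σ_st`, where `σ_st` counts
  geodesics from `s` to `t` and `σ_st(v)` those through `v` — how much the
  team's passing flow depends on the player as a bridge.

**Positional regularity.** From the 5 Hz tracking stream, the Euclidean
distance series of each of the 45 teammate dyads is summarised by Approximate
Entropy, `ApEn = Φ^m(r) − Φ^{m+1}(r)` with `m = 2`, `r = 0.2·SD` (max-norm
templates, self-matches included). Lower ApEn means a more regular,
predictable dyadic relation. A BIC-selected one-dimensional Gaussian mixture
classifies the 45 values into higher / medium / lower regularity.

**Dominant regions.** Every processed frame is tessellated into Voronoi
cells over the 20 outfield players of both teams, clipped to the 106 × 65 m
pitch; each player gets a mean area and a coefficient of variation.

**Statistical layer.** Between-team comparisons use pooled-variance
standardized differences with 90% confidence limits (thresholds 0.2 / 0.6 /
1.2 / 2.0 for trivial / small / moderate / large / very large), log-scale
percent differences for counts, magnitude-based inference labels
(25–75% possible, 75–95% likely, 95–99% very likely, >99% most likely;
"unclear" when the 90% interval spans substantial values of both signs),
Pearson correlations with Fisher-z intervals (scale 0.1 / 0.3 / 0.5 / 0.7 /
0.9), and shooting efficacy `goals × 100 / shots`.

**Synthetic matches.** Because raw tracking data of this kind is rarely
shareable, the package ships a generator that emulates the statistical
structure the analysis assumes: formation-anchored (1-4-3-3), ball-coupled
mean-reverting player movement with a tunable regularity knob, pass
sequences with tunable topology (uniform or hub-centred), and a plantable
negative correlation between dyad pass counts and dyad ApEn. Every
downstream stage is tested end to end against it.

## Worked example

```r
library(pitchnet)

cfg <- match_config(period_min = 5, seed = 42)       # two 5-min periods, 5 Hz
fx  <- make_match_fixture(cfg,
                          topology = pass_topology(n_passes = 450),
                          planted_rho = -0.4,
                          shots = c(6, 4), goals = c(2, 1))
rep <- run_match_analysis(fx)

cent <- rep$teams$home$centrality
head(cent[order(-cent$betweenness), ], 3)
#>   player_id closeness reachable_count betweenness
#> 1 home_RW       0.638               9           9
#> 2 home_RB       0.578               9           6
#> 3 home_LCB      0.634               9           5

rep$teams$home$correlation$directed
#> r = -0.43 [90% CI -0.56; -0.28], moderate (clear), n = 90

rep$between$closeness
#> d = -0.13 [90% CI -0.87; 0.60], trivial, unclear

rep$between$efficacy
#> home away
#> 33.3 25.0
```

Reading the output: `home_RW` is the bridge this team's passing flow depends
on most (betweenness 9 of the geodesic pairs' dependency); the directed
pass-count/ApEn correlation of −0.43 (moderate, clear) recovers the planted
coupling of −0.4 — dyads that exchange more passes hold more regular
positional relations; the between-team closeness difference is trivial and
unclear, as expected for two teams drawn from the same generator; the home
side converted 2 of 6 shots (efficacy 33.3%).

`write_match_report(rep, "out/")` writes the centrality, dyad and Voronoi
CSV tables, a GraphML export per team (for external network rendering), and
a JSON report. A thin command-line wrapper with `simulate` and `analyze`
subcommands is installed at `inst/cli/pitchnet.R`.

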