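Package: pitchnet
Title: Passing Networks and Positional Regularity Analysis for Team Sports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples notational and spatio-temporal analysis of team sports
    performance. Builds directed weighted passing networks from pass-event logs
    and computes geodesic closeness and betweenness centralities; computes
    dyadic positional regularity from player tracking via Approximate Entropy
    of teammate distance time series; derives dynamic Voronoi dominant regions
    clipped to the pitch with per-player mean area and coefficient of
    variation; classifies dyad regularity with a BIC-selected Gaussian
    mixture; and provides the magnitude-based-inference statistical layer
    (pooled-variance standardized differences with 90 percent confidence
    limits, log-scale percent differences, Fisher-z correlation intervals,
    qualitative magnitude labels). A synthetic-match generator with tunable
    dyad regularity, pass-network topology and a plantable pass-regularity
    correlation makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    tibble
Suggests:
    testthat (>= 3.0.0),
    mclust,
    geosphere,
    optparse,
    yaml
Config/testthat/edition: 3
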