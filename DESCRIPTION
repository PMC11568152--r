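Package: stagespec
Title: Habitat Specialization and Biodiversity Along Forest Development and Elevation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying habitat specialization of forest-dwelling
    taxa across forest developmental stages and elevational zones. Implements
    the reciprocal-Simpson niche-breadth index, a fixed-margin (curveball /
    trial-swap) null model for presence-absence matrices with a sign-flipped
    standardized effect size of specialization, per-plot species richness and
    cross-stage pairwise Jaccard dissimilarity, and a draw-based inference
    layer (Gaussian location-scale, negative-binomial and beta regressions
    with MAP, highest-density-interval, probability-of-direction and ROPE
    summaries, zone contrasts, averaged elevation effects and
    difference-of-differences). A synthetic metacommunity generator with a
    Dirichlet-Bernoulli occupancy model provides study designs and incidence
    tables with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmmTMB,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    withr
Config/testthat/edition: 3
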