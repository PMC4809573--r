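Package: riemdisc
Title: Inter-Temporal Discounting on Constant Negative Curvature Decision Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models inter-temporal choice as distance-driven discounting on a
    decision space of constant negative Gaussian curvature. Provides
    hyperboloid-model geometry primitives (Weierstrass coordinates, Minkowski
    inner products, geodesic distances), the leak-per-distance discount
    function and its instantaneous discount rate, executable demonstrations of
    classic discounting phenomena (common-difference preference reversal,
    temporal and monetary subadditivity, magnitude effect, preference for
    improving sequences), elicitation of latent pairwise distances from
    matching-task responses, simulated-annealing embedding algorithms that fit
    negative-curvature and Euclidean geometries to those distances and
    estimate the curvature, per-participant model classification with a cohort
    chi-square, and a synthetic-participant generator for end-to-end
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
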