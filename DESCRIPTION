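Package: greengrowth
Title: Green-Space-Aware Urban Growth Scenario Modelling and Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for building and ranking urban-growth
    scenarios that protect green-space cores and corridors. Segments a
    binary green-space mask into morphological classes (core, islet,
    perforation, edge, loop, bridge, branch), scores core patches with the
    probability-of-connectivity index and its per-patch importance (dPC),
    maps corridors as circuit-theory current over a conductance surface,
    folds importance and current into an urbanization-exclusion layer,
    simulates growth with a SLEUTH-style cellular automaton (diffusion,
    breed, spread, slope resistance, road gravity; diffusion-multiplier
    sweep, staged calibration against observed urban epochs, Monte-Carlo
    urbanization likelihood), constructs compact and social-equity
    scenario variants, quantifies scenario impacts on cores and corridors
    (affected fractions, PARA_MN, ENN_MN), and ranks scenarios with TOPSIS
    including a weight-perturbation robustness analysis. A synthetic
    landscape generator provides fully reproducible inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    EBImage,
    pROC,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
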