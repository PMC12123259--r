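Package: nichewire
Title: Trait-Based Interaction Niches and Network Rewiring Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts bipartite metanetworks of feasible species interactions
    from functional traits with boosted regression trees, quantifies
    fundamental functional interaction niches as convex-hull trait volumes
    (functional richness in a Gower/principal-coordinates trait space), and
    maps trophic-level rewiring potential over a species occurrence grid.
    Includes a synthetic two-trophic-level ecosystem generator with a known
    trait-matching feasibility kernel so every stage of the pipeline can be
    validated against ground truth, plus generalised additive model tools to
    decompose rewiring potential into richness and spatial effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
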