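Package: depauperon
Title: Classifying Clade Species Richness Under a Birth-Death Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies taxonomic families as species-poor, as-predicted, or
    species-rich given their crown age and species richness, using the
    geometric clade-size distribution implied by a constant-rate birth-death
    process. Provides grid maximum-likelihood estimation of net
    diversification rate and speciation rate per geological interval,
    profile-likelihood confidence intervals, stochastic clade-size bounds,
    cross-dataset strict and majority consensus calls, and a downstream
    statistical battery (Pearson chi-squared with Haberman adjusted
    residuals, Kruskal-Wallis with Dunn post-hoc under a global false
    discovery rate, Kolmogorov-Smirnov comparisons). Includes occurrence
    record cleaning, one-degree grid aggregation of family diversification
    rates, realm/biome range summaries, and a synthetic-data generator that
    emulates every input so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
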