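Package: groupsigma
Title: Structural Coefficients for Two-Strategy Games in Group-Structured
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact calculation of the structural coefficient (sigma) that
    quantifies how group structure shifts two-strategy competition under weak
    selection, for populations of any finite size distributed over groups on a
    circle with mutation and any isotropic migration pattern. Provides the
    closed-form coefficient with and without self-interaction, the
    large-population approximation for global migration, migration structure
    functions for arbitrary migration ranges, critical cost-to-benefit ratios
    for the prisoner's dilemma and snowdrift games, a frequency-dependent Moran
    process simulator with Monte-Carlo estimation of sigma under neutrality,
    and a brute-force Markov-chain oracle that verifies the closed forms on
    small populations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
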