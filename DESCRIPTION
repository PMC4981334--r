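Package: graphgames
Title: Evolutionary Multiplayer Games on Regular Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding when a strategy is favored under weak
    selection in d-player symmetric games played on graph-structured
    populations evolving by a Moran death-Birth process. Provides exact
    structure coefficients for cycles and well-mixed populations, a
    pair/diffusion approximation for regular graphs of degree three and
    larger, the multiplayer sigma rule with critical benefit-to-cost
    thresholds for volunteer's dilemmas and linear public-goods games,
    generators for the regular graph families used in simulation studies
    (rings, random regular graphs, toroidal lattices), a Monte Carlo
    fixation-probability simulator with a compiled core, and an exact
    Markov-chain solver for small graphs that serves as an oracle for the
    weak-selection theory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
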