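Package: domhier
Title: Dominance Hierarchy Analysis for Group-Housed Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dominance hierarchies in group-housed animals
    from timed winner/loser agonistic event logs. Builds win/loss sociomatrices
    (with a configurable co-occurrence priority rule), computes David's scores
    and hierarchy steepness, Landau's modified h', triangle transitivity,
    directional consistency, despotism and Gini coefficients, with
    randomization-based significance tests and QAP matrix-correlation tests;
    tracks rating dynamics event-by-event with the Glicko system; summarises
    hierarchy emergence day-by-day and estrous-state sequences; and simulates
    synthetic colonies with tunable linearity, despotism and estrus structure
    so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
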