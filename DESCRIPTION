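Package: myxoglide
Title: Mass-Spring Simulation of Gliding Myxobacteria with Head-to-Tail
    Guiding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional mass-spring simulation of flexible rod-shaped
    gliding bacteria (myxobacteria) on a periodic substratum. Cells are
    chains of particles joined by linear and angular springs, propelled by
    a distributed engine under overdamped drag, and interact through
    capsule collision response, three kinds of short-range head-to-tail
    guiding forces (adhesion, active following, passive following), and a
    long-range slime-trail field. Includes scenario builders (random,
    dense aligned, spiral aggregate), trajectory analysis (segment speeds,
    collision strain energies, aggregate detection, rigid-body rotation
    profiling), and a continuum rigid-body model predicting the edge speed
    of rotating circular aggregates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    purrr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
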