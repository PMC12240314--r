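Package: swinenet
Title: Livestock Movement Network Analysis from Permit Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds origin-destination networks from livestock movement
    permit records (Mexico's SENASICA-style swine permits) at state and
    municipal level, and computes the network and market statistics used
    in veterinary-epidemiological market studies: dichotomized adjacency,
    diagonal-inclusive network density, supply and demand degree
    centrality under configurable denominators, eigenvector prestige via
    hub/authority power iteration, market shares and top-k concentration,
    compound annual growth, trend correlation, location quotients and
    specialization coefficients, and a transport-duration compliance
    check. Includes a calibrated synthetic permit generator so the whole
    pipeline runs without access to the original permit database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    ggplot2
Config/testthat/edition: 3
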