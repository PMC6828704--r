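Package: dominet
Title: Dominance Hierarchies and Temporal Social Networks from Dyadic
    Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers temporal dominance hierarchies from dyadic agonistic
    interaction records by randomized Elo-rating and by David's scores,
    builds per-session directed, weighted, rate-normalized agonistic and
    affiliative social networks, and tests their consistency through time
    with quadratic assignment procedure (QAP) permutation tests. Includes
    a calibrated simulator of group interaction data with known ground
    truth for validating every stage of the analysis, and an end-to-end
    pipeline producing a machine-readable report.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
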