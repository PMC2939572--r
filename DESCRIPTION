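Package: mcnet
Title: Phylogenetic Split Networks from Distance Matrices by Simulated Annealing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs circular split networks from pairwise distance
    matrices. A greedy initial ordering followed by a Monte-Carlo simulated
    annealing search finds a circular ordering of the taxa that minimizes the
    closed-tour length under the input distances; the ordering's circular
    splits are then weighted by non-negative least squares, near-zero splits
    are discarded, and the weighted split system is written as a
    SplitsTree-readable NEXUS file. Includes seeded generators for additive
    (treelike) and circular (Kalmanson) test metrics and an exhaustive
    small-instance oracle for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    phangorn,
    pracma,
    jsonlite,
    withr,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo: Rcpp
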