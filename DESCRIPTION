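Package: yuledist
Title: Pairwise Distance Statistics on Random Yule Trees with Incomplete
    Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical theory of pairwise evolutionary time distances
    between the observed leaves of a birth-death (Yule) tree of fixed height
    with Bernoulli leaf sampling.  Provides exact closed-form expected
    densities for pairwise, n-th nearest-neighbour, cherry and pairwise
    minimum nearest-neighbour distances; the observed leaf-count law and
    branch-length moments; a Kinetic Monte Carlo tree simulator with full
    genealogy retention that validates the formulas; tree-free statistics
    computed directly from distance matrices (Newick, TSV or PHYLIP-square
    input); and robust iteratively reweighted least-squares fitting of the
    closed forms to distance histograms, reporting the three identifiable
    parameter combinations (net growth rate, birth rate times sampling
    fraction, expected leaf count) with derived bounds on the sampling
    fraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
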