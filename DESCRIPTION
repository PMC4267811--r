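Package: branchplan
Title: Phylogenetic Branches as Conservation Features in Reserve Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for systematic conservation planning with phylogenetic
    diversity (PD) as the biodiversity currency. Every branch of a rooted
    phylogeny is encoded as a presence/absence conservation feature across
    planning units, weighted by its relative length, and fed to a
    Marxan-style simulated-annealing minimum-set selector. Also provides
    the greedy summed-PD complementarity heuristic with averaged rankings,
    exact PD rarefaction (expected PD of planning units drawn uniformly
    without replacement), Marxan input-file interchange (pu.dat, spec.dat,
    puvspr.dat), and seeded generators of ultrametric Yule, stemmy and
    tippy trees with narrow-endemic occupancy for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
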