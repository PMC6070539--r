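Package: cladescape
Title: Individual-Based Simulation of Clade Diversification on Dynamic
    Fragmented Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-based eco-evolutionary simulator of clade
    diversification on a dynamic fragmented landscape, together with a
    macroevolutionary measurement layer. Organisms carry polygenic ecological
    and choosiness traits and accumulate neutral genetic incompatibilities
    under an infinite-sites model; mating is assortative on the ecological
    phenotype (a magic trait), competition is frequency-dependent with
    Gaussian kernels, and geographic barriers between habitat sites arise and
    disappear stochastically. The package delimits species under the
    biological species concept, tracks lineages through time, exports
    phylogenies of extant and extinct species, and estimates
    diversity-dependent speciation and extinction rates, stationary diversity,
    turnover, and macroecological summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    igraph,
    stats,
    utils,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
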