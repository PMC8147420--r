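Package: rmapasm
Title: De Novo Assembly of Optical Mapping Rmap Data with a Bi-Labelled de
    Bruijn Graph
Version: 0.1.0
Authors@R:
    person("Rmapasm", "Developers", email = "rmapasm@example.org",
           role = c("aut", "cre"))
Description: Assembles single-molecule restriction maps (Rmaps) into
    consensus contig optical maps. Error-tolerant bi-labels (two k-mers of
    fragment lengths separated by a length-bounded skip segment) are
    extracted from each Rmap, indexed in a disjoint forest of k-d trees for
    orthogonal range search, reduced to a proximal representative set, and
    assembled through a bi-labelled de Bruijn graph with tip and bubble
    removal followed by unitig extraction. A restriction-map simulator with
    a configurable error model (missed cut sites, spurious cut sites,
    length-dependent sizing noise) and an evaluation module (assembly
    statistics, genome fraction, fit alignment) make the whole pipeline
    testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
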