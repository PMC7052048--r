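Package: dlthist
Title: Counting and Sampling Gene Family Evolutionary Histories
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Enumerative and analytic tools for the space of gene family
    evolutionary histories constrained by a species tree, under models
    combining speciation, gene duplication, gene loss and horizontal gene
    transfer.  Provides dynamic-programming counting of histories of a
    given size for ranked and unranked species trees (models uDL, rDL,
    uDLT, rDLT and the speciation-loss variant rDT-SL), exact uniform
    random generation of histories by the recursive method, generating
    function machinery for the asymptotic number of duplication-loss
    histories (dominant singularity and leading constant, with closed
    forms for caterpillar and complete binary species trees), and the
    events-graph encoding that makes rDT-SL history counts independent of
    the species tree topology.  All counts are computed with exact
    arbitrary-precision integer arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
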