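Package: ribscreen
Title: Comparative Genomics and Regulation of Riboflavin Biosynthesis in
    Bifidobacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying the riboflavin (vitamin B2)
    biosynthesis gene cluster in Bifidobacterium: presence/absence calling of
    the ribDEABH operon across a genome panel from Smith-Waterman protein
    homology with Karlin-Altschul E-values and Markov clustering;
    neighbor-joining phylogenomics with bootstrap support and tanglegram
    entanglement scoring; FMN riboswitch motif detection, mutant point-mutation
    mapping and classification; relative expression by the 2^-ddCt method and a
    transparent negative-binomial differential-expression stage with
    median-of-ratios normalization; fermentation growth and production kinetics
    and bioassay calibration-curve quantification. Seeded synthetic-data
    generators emulate every input so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    ape,
    Biostrings,
    car,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
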