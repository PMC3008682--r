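Package: leafphylo
Title: Phylogenetic Signal and Phylogenetic Regression for Leaf
    Physiognomy-Climate Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether leaf physiognomic traits track
    climate independently of evolutionary history.  Assembles dated
    species-site phylogenies by grafting taxon lists onto a family-level
    backbone and spacing undated nodes evenly between dated ones,
    quantifies phylogenetic signal with Blomberg's K and a tip-shuffling
    permutation test on independent-contrast variances, and fits
    trait-temperature regressions by ordinary and lambda-scaled
    phylogenetic generalized least squares compared by AIC, including a
    penalized quasi-likelihood binomial model for leaf-margin state.  A
    seeded synthetic community generator emulates a species-site trait
    table on a temperature gradient so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    nlme,
    jsonlite
Config/testthat/edition: 3
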