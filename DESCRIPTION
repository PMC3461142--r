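Package: phylotox
Title: Phylogenetic Analysis of Tadpole Insecticide Sensitivity
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the comparative analysis of amphibian acute-toxicity
    assays. Estimates LC10/LC50/LC90 values with Fieller 84% confidence limits
    from grouped binomial mortality data by probit regression on log10
    concentration after Abbott control-mortality correction; detects
    post-exposure mortality time lags by an 84% confidence-interval overlap
    rule; quantifies phylogenetic signal in continuous sensitivity traits with
    Blomberg's K and a permutation test on the variance of phylogenetically
    independent contrasts; and reconstructs binary time-lag characters on
    phylogenies with a two-state equal-rates Markov model, counting
    evolutionary transitions against a tip-shuffle permutation null. Ships the
    endosulfan sensitivity tables for 15 tadpole species and 6 Rana sylvatica
    populations together with reference topologies, plus seed-stable
    generators for synthetic mortality tables, Brownian-motion traits and
    Markov binary characters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    multcomp,
    stats,
    utils
Suggests:
    phangorn,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
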