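Package: cytodiscord
Title: Cytonuclear Discordance and Chloroplast Capture Detection from
    Posterior Tree Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and classifying phylogenetic incongruence
    between nuclear and chloroplast gene trees, the signature of chloroplast
    capture and incomplete lineage sorting. Reads posterior tree samples from
    Bayesian MCMC runs (Newick lists or NEXUS trees blocks with translate
    tables), applies burn-in, builds majority-rule, strict and semi-strict
    consensus trees, pools two genomes' tree populations and annotates the
    combined consensus with internode certainty (IC), detects per-species
    supported conflicts at a posterior-probability threshold, measures
    topological node displacement to separate lineage-sorting candidates from
    hybridisation candidates, exports tanglegrams, and runs a permutation
    incongruence length difference (ILD) test on alignment partitions using
    Fitch parsimony. A synthetic-data module generates species trees with
    implanted capture events, posterior-like tree samples and alignments with
    a known truth table, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    readr,
    jsonlite,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
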