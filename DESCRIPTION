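Package: ohnologr
Title: Whole-Genome Duplication Aware Gene Family Evolution Analysis
Version: 0.1.0
Authors@R:
    person("Ohnologr", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing the evolution of gene families shaped
    by whole-genome duplications (WGD). Provides a genome-evolution
    simulator with WGD rounds, tandem duplication, loss, pseudogenization
    and rearrangement; Dollo parsimony gain/loss reconstruction on a
    species tree; LCA gene-tree/species-tree reconciliation with WGD-window
    timing of duplications; conserved-synteny comparison and paralogon
    (ohnolog quartet) detection from gene coordinate tables; and an
    event-propagation scenario engine that executes a per-branch event
    history to predict per-species gene repertoires. Ships a worked
    vertebrate TRPV ion-channel fixture (species tree, presence/absence
    matrix, event history) covering the 1R/2R, teleost 3R and salmonid 4R
    duplication rounds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
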