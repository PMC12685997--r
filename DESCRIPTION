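Package: aggmarkov
Title: Aggregated Markov Models for Ion-Channel Gating: Enumeration,
    Identifiability and Equivalence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for aggregated (two-class) continuous-time Markov models
    of ion-channel gating. Counts the distinct model topologies for a given
    number of states by exact Polya enumeration (cycle indices of the pair
    group, rooted-graph colourings, and the inverse Euler transform for
    connected graphs). Computes stationary distributions, detailed-balance
    diagnostics, open/closed sojourn-time mixtures of exponentials, bivariate
    dwell distributions and parameter-identifiability bounds. Implements
    block-wise similarity transformations, the Bauer-Kienker uncoupled
    canonical form and equivalence testing, the complete analysis of the
    fully connected three-state model (invariants, star and chain reductions,
    the continuous equivalence family, the detailed-balance curve and the
    signed-mixture regime), ligand-dependent rate transformations between
    star and chain topologies, and an exact stochastic simulator for
    dwell-time sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
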