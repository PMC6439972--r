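Package: RNAComplexes
Title: Multi-Strand RNA Complex Secondary Structure Prediction via
    Constrained Maximum-Weight Cliques
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts secondary structures of RNA complexes composed of
    several interacting strands, including internal pseudoknots and
    crossing interactions. Candidate secondary structures per strand and
    candidate interaction sites per strand pair are modelled as vertices
    of a compatibility graph weighted by nearest-neighbor free energies
    (Turner 2004 parameters; stacking-energy sums for pseudoknotted
    structures). Complexes correspond to constrained maximum-weight
    cliques (exactly one structure vertex per strand, no empty
    complexes), searched with a breakout local search heuristic that
    archives all valid cliques encountered, yielding ranked optimal and
    sub-optimal complexes after symmetry-aware deduplication. Includes a
    synthetic instance generator with plantable optima, an exhaustive
    enumeration oracle, and base-pair-level evaluation statistics
    (sensitivity, PPV, F1, MCC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
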