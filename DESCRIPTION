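Package: triadentropy
Title: Backbone Conformational Entropy and Disorder Prediction from Amino Acid Triads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise intrinsic disorder in proteins from
    sequence composition and backbone conformational entropy. Computes
    relative amino-acid and triad compositions with bootstrap confidence
    intervals to separate globular from intrinsically disordered sequences,
    bins backbone phi/psi dihedral angles on Ramachandran grids and derives
    Shannon conformational entropies residuewise and per amino-acid triad,
    predicts the conformational entropy of a chain from sequence alone via
    triad-entropy reference tables, validates predictions with a
    second-order mutual-information expansion, counts heavy-atom two-body
    contacts, and samples coarse-grained C-alpha ensembles with a
    constrained Metropolis Monte Carlo scheme.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
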