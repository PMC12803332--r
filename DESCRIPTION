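Package: sspot
Title: Secondary-Structure Likelihood Potentials from a Backbone Graph Neural Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a backbone-only multiscale graph neural network to predict
    per-atom eight-class (DSSP SS8) secondary-structure likelihoods by knowledge
    distillation from soft labels, converts those likelihoods into differentiable
    one-state and multi-state implicit-solvent energy functions with analytic
    forces, and propagates structures under the learned potential with a minimal
    Langevin dynamics engine. Includes a self-contained Kabsch-Sander SS8
    assigner, an idealized-backbone structure generator for controlled
    experiments, and PDB backbone input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
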