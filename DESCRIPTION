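Package: ifacelec
Title: Electrostatic Analysis of Protein-Protein Binding Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuum-electrostatics toolkit for protein-protein complexes.
    Solves the Poisson-Boltzmann equation on a regular grid with a
    finite-difference successive over-relaxation scheme, computes net
    electrostatic forces between two molecules along a center-of-mass
    separation scan with attractive/repulsive classification, and analyses
    hydrogen-bond and salt-bridge occupancies at binding interfaces over
    conformational ensembles. Includes synthetic fixture generators
    (analytically solvable Born ions, charge dumbbells, planted-contact
    trajectories) so every stage can be validated against closed forms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
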