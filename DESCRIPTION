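Package: confbias
Title: Biasing Conformer Ensembles Towards Bioactive-Like Conformations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to label, rank and select small-molecule conformers by their
    likeness to experimentally observed bioactive (target-bound) conformations.
    Conformer ensembles are generated with a seeded distance-geometry generator,
    labelled by the symmetry-aware heavy-atom RMSD to the closest bioactive
    reference (ARMSD_bio), and ranked either by a distance-based atomistic
    neural network trained to predict ARMSD_bio, by bioactivity-unaware
    descriptors (generation order, force-field energy, solvent-accessible
    surface area, radius of gyration, random), or by torsion fingerprint
    deviation over the maximum common substructure to the nearest reference
    molecule. Rankings are scored with early-enrichment metrics (BEDROC),
    with random and scaffold-cluster dataset splitting and a synthetic
    benchmark generator for fully self-contained evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (obabel, obenergy on PATH); Python 3 with RDKit
    (python on PATH) for conformer embedding
Config/testthat/edition: 3
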