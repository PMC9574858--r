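Package: protacfold
Title: Conformational Ensemble Analysis for Bifunctional Degrader Permeability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to rationalize the cell permeability of bifunctional
    degraders (PROTACs) from their solution conformational ensembles.
    Implements NOESY buildup analysis (initial-rate interproton distances
    against a geminal methylene reference), NAMFIS-style population
    deconvolution of time-averaged distance restraints with noise and
    jackknife validation, per-conformer and population-weighted ensemble
    descriptors (radius of gyration, solvent-accessible surface area and
    3D polar surface area, intramolecular hydrogen-bond counts), shape and
    clustering analysis (principal moments of inertia, Cartesian PCA,
    K-means, diverse-subset selection, folded/semi-folded/linear
    classification, RMSF), permeability surrogates from cellular and
    biochemical potencies, and a synthetic-data generator that builds model
    bifunctional molecules and NOE buildups with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    pracma,
    igraph,
    bio3d,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
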