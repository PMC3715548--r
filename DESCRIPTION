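Package: gnmswitch
Title: Elastic-Network Analysis of Hinge-Mediated Conformational Switches
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Gaussian Network Model (GNM) analysis of coarse-grained Calpha
    structures and conformer ensembles, aimed at hinge-mediated allosteric
    switches in two-domain proteins. Builds Kirchhoff contact matrices,
    computes mode-restricted mean-square fluctuations and normalized
    cross-correlation maps, detects hinges from slow-mode shapes and
    sign crossovers, compares functional states through difference-correlation
    maps and difference fluctuation profiles, scores hinge-mediated
    inter-subunit coupling into on/off switch states, clusters conformer
    series at a fixed radius with best-member extraction, and performs
    essential-dynamics (PCA) analysis of trajectory fluctuation matrices.
    Includes generators for synthetic chains, two-domain dumbbells, symmetric
    dimers, perturbed ensembles and two-state pseudo-trajectories with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
biocViews: StructuralBioinformatics, Proteomics, Clustering,
    PrincipalComponent, Network
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'methods.R'
    'gnm-core.R'
    'ensemble-analysis.R'
    'gnmswitch-package.R'
    'mode-analysis.R'
    'trajectory-analysis.R'
    'pipeline.R'
    'structure-io.R'
    'synthetic-data.R'
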