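Package: afqsar
Title: Ligand-Based QSAR Classification and Virtual Screening for
    Antifouling Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reimplements a ligand-based computer-aided drug design
    pipeline for antifouling activity of small organic molecules:
    strict MDL SDF V2000 molecule I/O with largest-fragment
    standardization and canonical-key deduplication, iterative
    electronegativity-equalization partial charges, a descriptor engine
    covering topological autocorrelations (Broto-Moreau, Moran, Geary),
    Burden-modified eigenvalues, electrotopological-state atom types,
    nitrogen weighted paths, Galvez topological charge indices, Mannhold
    LogP and charge-pair-partitioned 3D radial distribution function
    descriptors, class-balanced random-forest QSAR models with
    out-of-bag importance-based descriptor selection, SVM and multilayer
    perceptron comparators, the SE/SP/Q/MCC evaluation protocol with
    rate-to-count inversion audits, probability-threshold virtual
    screening triage, and a synthetic molecule-library generator with a
    planted structure-activity rule for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    randomForest,
    e1071,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ChemmineR
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
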