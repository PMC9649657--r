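Package: nmrem
Title: Integrative NMR Distance-Restraint and Cryo-EM Density Structure Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for integrative structure determination of
    proteins bound to large assemblies, combining solid-state NMR carbon-carbon
    distance restraints with medium-resolution cryo-EM density maps. Converts
    assigned cross-peaks into classified, non-redundant ambiguous distance
    restraints; performs restrained simulated annealing of a single chain with
    flat-bottom distance, dihedral, covalent-geometry and density
    cross-correlation energy terms; docks the refined chain into a density map
    at multiple positions by rigid-body search; jointly refines a multi-copy
    assembly under non-crystallographic-symmetry restraints; locally refines a
    mobile segment against extra restraints; and computes ensemble validation
    statistics (restraint violations, idealized-geometry deviations, pairwise
    RMSD). A synthetic-data module generates toy folds, labeling-scheme-filtered
    peak lists, torsion restraints, multi-copy lattices and density maps with
    known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
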