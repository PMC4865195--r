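Package: dockscore
Title: Empirical Protein-Ligand Scoring Functions, Pose Minimization and
    Screening Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Vina and Vinardo families of empirical
    protein-ligand scoring functions as pairwise atom-type potentials
    (Gaussian steric attraction, quadratic overlap repulsion, piecewise
    linear hydrophobic and non-directional hydrogen-bond terms, optional
    generic m-n Lennard-Jones), together with the machinery needed to use
    and develop such functions at desk scale: an AutoDock PDBQT
    reader/writer with torsion-tree support, BFGS pose minimization over
    rigid-body and torsional degrees of freedom, symmetry-corrected RMSD
    via optimal within-type atom assignment, CASF-style scoring, ranking,
    docking and screening power statistics, ROC AUC and BEDROC enrichment
    metrics, a constrained parameter-grid training screen driven by
    post-minimization RMSD, and deterministic synthetic fixture
    generators for receptors, ligands, pose decoys and labeled screening
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
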