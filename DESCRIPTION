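Package: posepop
Title: Binding-Pose Populations and Competition-Binding Analytics for
    Fragment Ligands of YTH Reader Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for characterising how small-molecule
    fragments bind the m6A-recognition pocket of YTH reader domains
    (YTHDF2 and paralogues).  Infers binding-pose clusters from
    molecular-dynamics trajectories (bound-frame selection by a
    sulfur-to-C433 distance criterion, featurization into ten
    protein-ligand distances, principal-component projection, and
    full-covariance Gaussian-mixture clustering with pose populations,
    centroid poses, and ligand-RMSD stability series); triages docking
    hits by dual energy-term ranking and pharmacophoric hydrogen-bond
    filters; and analyses competition-binding assays (residual-signal
    triage, four-parameter-logistic IC50 fitting, Cheng-Prusoff Kd
    conversion, ligand efficiency, and selectivity ratios).  A
    synthetic-data module generates trajectories, docking poses, and
    dose-response panels with known ground truth so that every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
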