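Package: poseval
Title: Binding-Pose Stability Scoring and Validation for Protein-Ligand
    Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for deciding whether a docked protein-ligand binding
    pose is trustworthy.  Scores candidate poses for stability from
    ensembles of (biased or unbiased) molecular-dynamics trajectories
    using metadynamics-style PoseScore/PersScore/CompScore statistics,
    deduplicates poses with structural interaction fingerprints (SIFt)
    and Tanimoto contact similarity, estimates binding free energies
    with a generalized Born / surface-area (MM/GBSA) model, clusters
    trajectory frames to extract representative conformations, and
    classifies pose reliability (confirmed / refined / ambiguous).
    Includes a minimal RMSD-collective-variable metadynamics engine for
    desk-scale validation, dose-response (IC50) triage arithmetic for
    screening campaigns, and deterministic synthetic-fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
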