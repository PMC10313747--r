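Package: sietraj
Title: Solvated Interaction Energy and Conformational Landscape Analysis of
    Protein-Ligand Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for molecular-dynamics trajectories of
    receptor-ligand complexes: Kabsch superposition with RMSD/RMSF metrics,
    Shrake-Rupley solvent-accessible surface area with a ligand-proximal
    shell, geometric hydrogen-bond and atom-contact criteria with occupancy
    statistics, solvated interaction energy (SIE) binding free energies with
    a generalized-Born reaction-field term, per-residue energy decomposition
    with a key-residue filter, and two-dimensional free-energy landscapes by
    Boltzmann inversion with basin detection and open/close gate
    classification.  Includes seeded synthetic-data generators that emulate a
    two-state gating receptor and scripted ligand interactions, so that the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
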