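Package: aptaprof
Title: Non-Covalent Interaction Profiling of Ligand-Aptamer MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-frame geometric detection of non-covalent interactions
    (hydrogen bonds, water-mediated hydrogen-bond bridges, pi-stacking,
    hydrophobic contacts) between a small-molecule ligand and a
    single-stranded DNA aptamer across a multi-model PDB trajectory,
    together with trajectory-level structural statistics (radius of
    gyration, Kabsch-superposed RMSD, RMSF, intramolecular hydrogen-bond
    counts), minimum inter-residue distance maps, secondary-structure
    annotation from base-pair lists, frequency aggregation reports, and a
    per-residue gas-phase molecular-mechanics (Coulomb + Lennard-Jones)
    interaction-energy decomposition. Includes a synthetic-fixture
    generator that plants geometrically exact interactions in small
    receptor-ligand-water systems with rigid-body motion, and a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
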