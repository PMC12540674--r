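Package: confswitch
Title: Conformational Switch Analysis and Free-Energy-Guided Enzyme Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-simulation analysis chain for substrate recognition in
    Ca2+-dependent O-methyltransferases and similar enzyme systems:
    Kabsch superposition, RMSD/RMSF primitives, Daura-style conformational
    clustering, principal-component free-energy landscapes by Boltzmann
    inversion, MM/PBSA component algebra with per-residue decomposition,
    solvated interaction energy (SIE) scoring, segmented-Jarzynski and
    WHAM potential-of-mean-force estimation, pore-radius profiling of
    substrate channels, and a dual free-energy-criterion screen for
    low-activity mutant design. Includes seeded synthetic-data generators
    so the whole pipeline is testable without trajectory downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
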