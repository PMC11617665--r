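Package: repurposekit
Title: Drug-Repurposing Screen Analytics: Library Curation, Chemotype
    Overlap, Consensus Docking Funnels, Inhibition Kinetics and
    Trajectory Post-Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable analysis components for structure-based drug
    repurposing screens against enzyme targets such as the protein
    tyrosine phosphatase 1B (PTP1B). Curates compound libraries
    (molecular-weight window, canonical deduplication, activity
    threshold), decomposes molecules into Bemis-Murcko chemotypes with
    retention of exocyclic double-bonded groups and selects
    search-library compounds sharing chemotypes with a reference set of
    actives, normalizes and aggregates docking scores from several
    programs into a quartile-gated consensus ranking, fits
    dose-response (IC50) and global Michaelis-Menten inhibition models
    (Vmax, Km, Ki) with AICc-based mechanism discrimination and
    Lineweaver-Burk diagnostics, and post-processes coordinate
    trajectories and MM/PBSA component tables (Kabsch superposition,
    RMSD, RMSF, contact-residue occupancy, binding-energy combination).
    A synthetic-data module generates every input with planted ground
    truth so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    minpack.lm,
    bio3d,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
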