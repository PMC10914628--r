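Package: adppi
Title: Active-Site Geometry and Phosphate-Release Analysis for AAA+ ATPase
    Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis layer for molecular-dynamics trajectories and models of
    the post-hydrolysis ADP.Pi intermediate of AAA+ ATPases such as p97.
    Reads multi-MODEL PDB trajectories, featurizes nucleotide-binding
    pockets (arginine-finger binding geometry d1/d2, F360 chi1 rotamer,
    Walker-motif engagement distances, Mg2+ coordination shells), classifies
    per-frame pocket states (ATP-like, ADP.Pi state A/B, ADP-like,
    apo+2Pi mimic), scores geometric hydrolysis competence, maps phosphate
    dissociation pathways (contact counting, residue ranking, waypoint
    traces, channel charge lining), computes per-residue RMSF mobility maps
    and sensor-loop 3-10-helix content, and performs a simplified
    single-trajectory Coulomb/Lennard-Jones interaction-energy decomposition
    for the leaving phosphate. Ships a synthetic active-site generator with
    planted ground truth so the whole pipeline is testable without external
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
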