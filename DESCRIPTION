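Package: gpcrprofiler
Title: Activation-State Geometry and G-Protein Interface Profiling for
    GPCR Structures and Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the structural hallmarks of class-A
    G-protein-coupled receptor (GPCR) activation and receptor-G-protein
    coupling. Provides generic residue numbering (Ballesteros-Weinstein for
    receptor transmembrane helices, CGN for G-alpha), least-squares rigid-body
    superposition and RMSD, minimum heavy-atom inter-residue distances,
    activation-hallmark metrics (DRY salt-bridge state, TM6 outward movement,
    TM7 axial displacement, the 3.46-7.53 gap), receptor-G-alpha interface
    contact enumeration with hydrogen-bond and van der Waals classification,
    per-frame trajectory statistics including hydrogen-bond occupancy and a
    grid-based water-occupancy density estimator, and fitting of
    concentration-response (pEC50/span) and one-site saturation-binding
    (Kd/Bmax) assay data. A synthetic-data generator builds helix bundles,
    two-chain interfaces, hydration trajectories and assay tables with known
    ground truth so every stage can be validated without external downloads.
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
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
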