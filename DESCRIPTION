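Package: vscascade
Title: Hybrid Deep-Learning and Physics-Based Virtual-Screening Cascade
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: A multi-stage structure-based virtual-screening toolkit: substructure
    sentence embeddings of ligands and binding pockets, a dense fully connected
    binding-probability classifier over normalized pocket-ligand pair vectors,
    protein-ligand interface featurization with a residual pose classifier,
    AutoDock-Vina-style docking configuration and log parsing with a deterministic
    mock engine, a threshold cascade over per-compound score tables, screening
    enrichment statistics, chemotype clustering of candidates, and post-analysis
    of molecular-dynamics and metadynamics outputs (RMSD, hydrogen bonds,
    free-energy reconstruction from Gaussian hills). Includes seeded synthetic
    data generators with planted binding signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
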