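Package: insrtr
Title: Insertion-Site Prediction and Equilibrium Simulation for
    Coiled-Coil Allosteric Protein Switches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts and ranks loop insertion sites for coiled-coil
    allosteric switches from a protein 3D structure. Computes bespoke
    structural descriptors (Shrake-Rupley solvent accessibility,
    hydrogen-bond based secondary structure, active-site distances),
    applies heuristic admissibility rules for candidate loops, trains a
    gradient-boosted classifier with nested leave-one-out
    cross-validation and permutation feature importance, and simulates
    the switch mechanism itself: helix-extension strain, OFF/ON
    competition equilibria of tethered coiled-coil peptides,
    protease-input two-input Boolean logic gates, and Hill kinetics
    fitting. Deterministic synthetic fixtures (toy structures, planted
    labeled tables, noisy curves) make the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    pROC,
    stats,
    utils,
    xgboost
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
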