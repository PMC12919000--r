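Package: ubiqpair
Title: Structure-Guided Assessment of Ubiquitin-E2-E3 Ternary Complexes and
    Prediction of Functional E2-E3 Pairs
Version: 0.1.0
Authors@R:
    person("UbiqPair", "Developers", email = "ubiqpair@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing ubiquitin-E2-E3 ternary complex structures,
    experimental or predicted. Reads PDB/mmCIF coordinates, assigns chain
    roles by sequence identity, classifies each complex as Closed or Open
    from the ubiquitin Ile44 to E2 crossover-helix distance (and the
    ubiquitin tail to catalytic-cysteine distance for predicted models),
    extracts interface features (hydrogen bonds, linchpin residues, E3 loop
    engagement, interface RMSD via Kabsch superposition), computes
    interface-confidence scores (mean interface PAE, ipSAE, pDockQ, pDockQ2,
    ipTM) from prediction-confidence JSON, constructs labelled pair/non-pair
    E2-E3 datasets from interaction edge tables, and trains a
    gradient-boosted decision-tree classifier with nested stratified
    cross-validation to predict functional E2-E3 partners. Includes
    deterministic synthetic-fixture generators for every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
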