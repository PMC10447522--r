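Package: shbligand
Title: Detection and Classification of Short Hydrogen Bonds in
    Protein-Ligand Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects hydrogen bonds between amino acid side chains and
    small-molecule ligands in atomic protein structures using geometric
    criteria (O/N heteroatoms, donor-acceptor distance 2.3-3.2 Angstrom,
    donor-H-acceptor angle >= 135 degrees), distinguishes short hydrogen
    bonds (R <= 2.7 Angstrom) from normal ones (R >= 2.8 Angstrom),
    featurizes each contact with 14 chemical and sequence descriptors,
    and classifies it with an ensemble of gradient-boosted tree models
    trained on class-balanced undersamples. Includes evaluation
    (precision/recall sweeps, ROC/AUC, feature importance), descriptive
    propensity statistics, and synthetic structure and feature-table
    generators with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    xgboost,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
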