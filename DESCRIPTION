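Package: vinaforest
Title: Random-Forest and Linear Rescoring of Protein-Ligand Complexes from
    Vina Energy Terms and Element-Pair Contact Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-ligand binding affinity (pKd/pKi) from X-ray
    co-crystal poses. Featurizes complexes with the five AutoDock Vina
    intermolecular energy terms plus the ligand rotatable-bond count, and
    with the 36 RF-Score intermolecular element-pair occurrence counts.
    Fits multiple linear regression and random-forest scoring functions
    with out-of-bag-driven mtry selection over seeded model instances,
    and evaluates them with CASF-style scoring-power metrics (RMSE, SD in
    linear correlation, Pearson and Spearman correlations). Includes a
    PDBbind-style index curation toolkit (refined-set quality criteria,
    resolution and Kd/Ki quality tiers, blind time-stamped splits),
    reproducible benchmark presets, and a synthetic complex/label/index
    generator so the full pipeline is testable without any database
    download.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
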