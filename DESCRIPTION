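Package: cas9nanoenv
Title: CRISPR-Cas9 Cleavage-Activity Prediction from the Heteroduplex-Proximal Protein Nanoenvironment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts CRISPR-Cas9 (off-)target cleavage activity from
    residue-resolved physico-chemical and structural descriptors of the
    protein nanoenvironment surrounding the sgRNA-tsDNA heteroduplex.
    Provides extraction of heteroduplex-proximal residues (HPRs) from PDB
    trajectory snapshots, heteroduplex base-pair geometry and plasticity
    measures, assembly of labelled residue-by-descriptor feature matrices,
    a three-step regression pipeline (standardisation, surrogate-importance
    feature selection, final regressor) with grid-searched model pairs and
    a Spearman-change rule for feature-set sizing, Shapley-value model
    interpretation with grouped importances and spatial residue-hotspot
    clustering, per-site RMSD stability series compared through Gaussian
    Kullback-Leibler divergence, and a seeded synthetic-data generator with
    planted informative features for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
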