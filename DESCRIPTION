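Package: RNAInterface
Title: Prediction of Protein-RNA Interface Residues from Evolutionary
    Sequence Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for structure-derived annotation and sequence-based
    prediction of protein-RNA interface residues. Annotates interface
    residues in protein-RNA complex structures by an atom-distance
    cutoff, encodes protein sequences as sliding windows over
    logistic-normalized position-specific scoring matrices (PSSMs),
    trains naive Bayes, random forest and support vector machine
    classifiers together with an SVM/forest consensus predictor, and
    evaluates them with chain-level cross-validation (accuracy,
    sensitivity, specificity, Matthews correlation and ROC AUC).
    Also provides profile distance metrics (normalized squared distance
    and symmetrized Kullback-Leibler divergence), seeded uniform
    subsampling of FASTA reference databases for faster PSI-BLAST
    profile generation, and synthetic fixture generators for fully
    offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    e1071,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
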