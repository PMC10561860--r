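Package: hairpinclass
Title: Feature Extraction and Machine-Learning Classification of
    pre-miRNA Hairpins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for distinguishing true precursor-microRNA hairpins
    from pseudo hairpins in insect genomes. Computes an ordered
    93-feature descriptor for a (sequence, secondary structure) pair:
    triplet sequence-structure elements, mono- and dinucleotide
    composition, stem/loop motif counts, and minimum-free-energy and
    ensemble (base-pair probability) thermodynamic indices. Provides
    dataset assembly with length/MFE/GC filtering, stratified
    train/test splitting, SMOTE oversampling and Near-Miss
    undersampling for class imbalance, training and coordinate-wise
    hyperparameter tuning for SVM, random forest, logistic-regression
    and k-nearest-neighbour classifiers, a confusion-matrix metric
    suite (sensitivity, specificity, precision, F1, MCC, trapezoidal
    AUC, AUPRC), and extraction of mature-miRNA arm candidates from
    predicted precursor hairpins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    ranger,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
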