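Package: dtiforest
Title: Drug-Target Interaction Prediction with Sequence Descriptors,
    Wrapper Feature Selection and Rotation Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature-based prediction of drug-target interactions (DTIs) from
    protein sequences and drug substructure fingerprints. Implements ten
    fixed-length protein sequence descriptors (EAAC, EGAAC, DDE, TF-IDF,
    1-gram, 2-gram, NUM, BINA, PSSM, PsePSSM, PseAAC), assembly of labeled
    drug-protein pair feature matrices from PubChem 881-bit fingerprints and
    interaction lists, symmetric-uncertainty feature ranking with incremental
    wrapper subset selection with replacement (IWSSR), a Rotation Forest
    ensemble classifier built from block-diagonal principal-component rotation
    matrices, and a stratified cross-validation / independent-split evaluation
    harness with ROC and Matthews correlation. Seeded synthetic-data
    generators with a planted feature-to-label signal allow the whole pipeline
    to be exercised and tested without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
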