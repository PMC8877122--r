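Package: snapqsar
Title: Image-Based QSAR from Multi-Angle Molecular Snapshots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-based quantitative structure-activity relationship (QSAR)
    pipeline for agonist/antagonist screening data. Curates SMILES libraries with
    PubChem-style 0-100 activity scores, generates MMFF94-minimized 3D conformers,
    renders deterministic ball-and-stick snapshots at user-defined angle increments
    about the x-, y- and z-axes, trains a small image classifier with early stopping
    and lowest-validation-loss model selection, aggregates per-image probabilities to
    per-molecule scores by the median, selects the classification cutoff by Youden's
    index, and reports sensitivity, specificity, balanced accuracy, F, MCC, ROC and
    precision-recall AUCs. Includes replicate parameter sweeps over snapshot angle,
    data-split ratio, learning rate and batch size, and a synthetic fixture generator
    with an image-learnable structure-activity rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    png,
    jsonlite,
    rlang,
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on the PATH
Config/testthat/edition: 3
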