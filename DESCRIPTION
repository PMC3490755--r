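Package: rnaiface
Title: Sequence and Structure Based Prediction of Protein-RNA Interface
    Residues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Distance-based labeling of RNA-binding residues in protein-RNA
    complex structures, six sliding-window feature encodings built on
    PSI-BLAST position-specific scoring matrices (identity, PSSM and
    smoothed-PSSM channels over sequence or spatial-neighbor windows),
    Naive Bayes and support vector machine classifiers, and a sequence-based
    cross-validation harness with residue-based and protein-based
    evaluation, ROC/PR/AUC analysis, tie-averaged rank comparison and a
    solvent-accessibility surface post-filter. Includes readers for PDB
    coordinates, FASTA, PSI-BLAST ASCII PSSM and NACCESS-style RSA tables,
    and a deterministic synthetic benchmark generator with planted
    interface signal so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    kernlab,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
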