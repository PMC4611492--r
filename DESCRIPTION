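Package: propseaac
Title: Profile-Based Pseudo Amino Acid Composition for DNA-Binding Protein
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies DNA-binding proteins from sequence alone by combining
    evolutionary frequency profiles with pseudo amino acid composition
    (PseAAC). A per-protein frequency profile (parsed from PSI-BLAST ASCII
    output or built from a multiple alignment with BLOSUM62 pseudo-counts) is
    collapsed to a profile-consensus sequence, which is converted into a
    (20 + lambda)-dimensional PseAAC feature vector using seven normalized
    physicochemical properties. Classification uses a radial-basis-function
    support vector machine with jackknife evaluation (sensitivity,
    specificity, accuracy, Matthews correlation coefficient, ROC/AUC),
    per-feature discriminant weights, and a probability-averaging ensemble
    over disjoint negative-sample subsets for imbalanced training pools.
    Includes a synthetic-data generator for end-to-end testing and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    kernlab,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
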