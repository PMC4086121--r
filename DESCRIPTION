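Package: nppred
Title: Neuropeptide Precursor Prediction from Protein Sequences
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate neuropeptide precursors (NPPs) in protein
    FASTA input. Sequences are converted into a fixed 560-dimensional
    descriptor vector (amino-acid composition, bigram frequencies and a
    catalog of 140 physicochemical and statistical descriptors) and scored
    by a four-model supervised ensemble (random forest, gradient boosting,
    probability-calibrated linear SVM and a minimal-feature tree model)
    with per-model probability thresholds. Dibasic and tribasic cleavage
    motifs are located along each sequence and summarised as an Internal
    Score, the motif density over the effective length after trimming a
    typical signal-peptide length, which ranks positive predictions and
    gates a high-quality subset. Includes a synthetic precursor generator
    with planted cleavage motifs for training and benchmarking, an optional
    signal-peptide filter (built-in heuristic or external predictor), and
    ggplot2 visualisations of motif architecture and feature distributions.
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
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    xgboost,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
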