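Package: chidt
Title: Donor Splice-Site Prediction with Chi-Square Compressed Decision Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts donor splice sites from short (11 bp) GT-anchored
    sequence windows using a decision-table classifier built from
    chi-square-compressed contingency tables. Per-feature 2 x r tables are
    greedily merged under a local chi-square stopping rule, features are
    introduced iteratively by gain ratio among above-average information
    gains, and class imbalance is handled by reweighting the table's
    negative counts so both classes carry equal mass. Classification
    perturbs the matched rule by one count under each class hypothesis and
    compares the resulting whole-table chi-square statistics. Includes
    positional and dinucleotide-composition feature encoding, per-position
    importance profiling, candidate-site scanning of genomic FASTA,
    evaluation metrics (sensitivity, specificity, MCC, Q9, ROC and
    Davis-Goadrich precision-recall AUC), stratified k-fold utilities, and
    a synthetic donor-site data generator with indel mutation for offline
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
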