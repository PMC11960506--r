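Package: dosegrammar
Title: Quantifying and Explaining Regulatory-Element Responses to Transcription Factor Dosage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how chromatin accessibility at regulatory
    elements responds to titration of transcription factor (TF) dosage.
    Fits per-element Hill dose-response curves with a modified, capped ED50
    and AIC-based model selection; implements an equilibrium model of
    TF-nucleosome competition (nucleosome-mediated cooperativity) with
    forward accessibility curves, theoretical ED50 analysis, sensitizing
    affinity-ratio thresholds, and least-squares fitting recipes; and maps
    individual motif instances from contribution-score tracks using
    contribution weight matrix (CWM) scanning with percentile thresholds,
    overlap resolution, and exact-p-value position weight matrix scanning.
    A synthetic-data module generates titration series, contribution tracks
    and sequences with recorded ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
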