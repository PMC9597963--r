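Package: guideboost
Title: Boosted-Tree Prediction of CRISPR-Cas9 Cleavage Efficiency from
    Expanded Target Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts wild-type SpCas9 on-target cleavage efficiency for
    single guide RNAs from 30-nt expanded target sequences (4-nt upstream
    context, 20-nt spacer, NGG PAM, 3-nt downstream context). Engineers 149
    sequence and thermodynamic features (k-mer counts, poly-T terminator
    statistics, position-specific mono- and dinucleotides encoded as native
    categorical variables, nearest-neighbor melting temperatures, RNA
    minimum-free-energy via RNAfold), harmonizes efficiency screens measured
    on different scales by affine rescaling fitted on overlapping guides,
    trains gradient-boosted regression trees with fixed-fold cross-validation,
    early stopping and Bayesian hyperparameter optimization, and produces
    interpretable outputs: normalized gain importance, per-prediction additive
    contribution breakdowns, and regression-tree exports with branch-mean
    internal values. Includes a synthetic screen generator with planted
    sequence effects for end-to-end validation, and a dependent-correlation
    (Steiger) test harness for comparing predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    xgboost
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
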