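Package: trikrr
Title: Three-Step Kernel Ridge Regression for Drug-Drug Interaction
    Effect Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts effects caused by drug-drug interactions as triplet
    link prediction on a symmetric binary (drug, drug, effect) label
    tensor. Implements three-step kernel ridge regression fitted by three
    tensor contractions through cached eigendecompositions, the four
    cold-start cross-validation schemes (held-out triplets, pairs, single
    drugs, drug pairs), macro-averaged per-effect and per-pair AUC
    evaluation, nested tuning of the three regularization parameters on
    log-spaced grids, and a 3-sigma rule for flagging candidate new
    interaction effects. Includes a synthetic generator emulating the
    shape of pharmacovigilance combination data and readers for the
    Decagon combo/mono CSV dialects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
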