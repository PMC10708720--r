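Package: coordwalk
Title: EEG Coherence-Graph Embeddings for Predicting Tacit Coordination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for predicting whether two players of a tacit
    coordination game converged on the same choice from the similarity of
    their EEG spatial coherence patterns. Multichannel epochs are band-pass
    filtered, average-referenced, baseline-corrected and downsampled; each
    epoch is reduced to a binary inter-electrode coherence graph (Welch
    magnitude-squared coherence thresholded at 0.5), embedded as a
    probability distribution over anonymous random-walk patterns, and player
    pairs are classified with gradient-boosted trees under stratified
    cross-validation. Includes the coordination index (CI) difficulty
    statistic, per-game precision/recall/F1 with CI regressions, and a
    synthetic-study generator with controllable focal-point saliency and
    inter-channel coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    pROC,
    signal,
    stats,
    tools,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
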