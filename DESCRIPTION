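Package: mazenav
Title: Belief Filtering, Confidence-Dependent Strategy Switching, and
    Pattern Decoding for Partially Observable Maze Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying scene prediction and confidence during
    navigation of a partially observable grid maze. Provides the maze
    environment and task protocol (action trials interleaved with
    four-option scene-prediction trials and four-level confidence
    reports), a hidden Markov behavioral model that filters a belief
    over hidden states together with a binary state-confidence variable
    and switches between a forward-dominant and an efficient-exploration
    action strategy, type-II maximum-likelihood fitting of the model with
    AIC-based model comparison, generative simulation of synthetic
    subjects, the behavioral statistics of the task (accuracy by
    confidence, trial-index trends, streak analysis, reaction-time
    normalization, subject exclusion), a generator of trial-wise
    multivariate activity patterns whose variability depends on
    confidence, and a time-resolved multiclass decoding pipeline with
    undersampling, sparse one-versus-rest classifiers, leave-one-session
    and leave-one-game-out cross-validation, conditional decoders, and a
    two-step group permutation test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
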