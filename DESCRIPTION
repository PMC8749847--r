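Package: gaitmood
Title: Gait-Based Emotion Recognition with Joint-Relative Features and a
    Tapered LSTM-MLP Network
Version: 0.1.0
Authors@R:
    person("gaitmood", "developers", email = "gaitmood@example.org",
           role = c("aut", "cre"))
Description: Classifies the emotion (angry, happy, sad, neutral) expressed
    by a walking person from motion-capture skeleton sequences. Implements
    handcrafted joint-relative geometric features (joint relative angles at
    the mid-spine and pairwise joint relative distances), a bi-modular
    sequential neural network (a tapered three-layer LSTM sub-network
    followed by a tapered three-layer MLP with softmax output) with a
    from-scratch, fully seeded training engine (RMSprop, categorical
    cross-entropy, optional batch normalization and dropout), stratified
    splitting for imbalanced classes, micro/macro mean-average-precision
    evaluation, and a kinematic synthetic gait generator so the whole
    pipeline is testable without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
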