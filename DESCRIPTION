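Package: emgseq
Title: Muscular Activation Sequences from Transient-State Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Feature extraction and classification of hand gestures from the
    transient state of multichannel surface-EMG envelopes. Implements
    double-threshold onset detection (rest-statistics low threshold with a
    sustain rule), per-task activation-threshold ladders with an exhaustive
    combinatorial search for the representative high-threshold vector,
    ordinal encoding of muscular activation sequences, the refined 12-element
    per-acquisition feature, four reference classifiers (non-linear logistic
    regression, support vector machine, multilayer perceptron, one-vs-all
    linear discriminant analysis), envelope-based transient and steady-state
    baseline features, offline accuracy and timing comparisons, and an online
    simulation reporting motion completion rate and motion selection time.
    A synthetic envelope generator with known onsets, activation orders and
    inactive channels makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    MASS,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'synthetic.R'
    'io.R'
    'onset.R'
    'thresholds.R'
    'encoding.R'
    'baselines.R'
    'mlp.R'
    'classification.R'
    'evaluation.R'
    'pipeline.R'
    'emgseq-package.R'
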