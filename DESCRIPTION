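Package: megdiverge
Title: Localizing Divergences Between Language-Model Embeddings and MEG
    Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-resolved ridge encoding models that predict word-locked
    MEG sensor responses from language-model embeddings, fitted with
    contiguous 10-fold cross-validation and nested regularization
    selection.  On top of the fitted model the package computes a
    per-word divergence statistic (mean squared prediction error over
    the significance-gated sensor/time grid), ranks sentences by it,
    builds contrast corpora of least- versus best-predicted sentences,
    and runs a proposer/verifier framework that discovers and
    permutation-tests natural-language hypotheses about how the corpora
    differ.  A model-comparison layer scores multiple-choice items as N
    language-modeling tasks, trains a toy sequence scorer by
    cross-entropy over option scores, and compares base versus
    fine-tuned encoding models with per-channel permutation tests and
    FDR-corrected category-wise MSE-improvement analyses.  A seeded
    synthetic-data generator with planted ground truth (known forward
    model, divergent word category, discoverable corpus difference,
    separable multiple-choice rule) makes every stage testable without
    neuroimaging downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
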