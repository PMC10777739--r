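Package: rxnyield
Title: Reaction Yield Prediction with Condition-Contrastive SMILES Pretraining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts chemical reaction yields from reaction SMILES with a
    small BERT-style transformer encoder trained in two self-supervised
    stages: masked-language-model pretraining over reaction tokens, then a
    combined objective that adds a reaction-condition contrastive loss
    (positives are randomized-SMILES re-serializations of the same reaction,
    negatives replace reagents, solvents or catalysts). Includes reaction
    table I/O and canonicalization, a regex reaction tokenizer, reaction-group
    machinery with yield binning and group-stratified splits, a synthetic
    reaction-corpus generator with known ground truth, fine-tuning heads for
    yield regression and 4-class yield classification, Reptile-style
    meta-learning over reaction categories for low-data classes, evaluation
    metrics, and yield-incorporated prior scoring for ranking single-step
    retrosynthesis expansions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
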