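# Shared fixtures, memoised so expensive objects (corpora, pretrained toy
# models) are built once per test run.

.fx_env <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fx_env, inherits = FALSE)) {
    assign(name, force(expr), envir = .fx_env)
  }
  get(name, envir = .fx_env)
}

# A mid-sized corpus with condition-driven yield structure.
fx_corpus <- function() fx("corpus", {
  generate_corpus(corpus_spec(n_groups = 30, conditions_per_group = c(3, 6),
                              condition_effect_sd = 10, noise_sd = 2,
                              seed = 42))
})

fx_vocab <- function() fx("vocab", build_vocabulary(fx_corpus()$records$reaction_smiles))

# Tiny encoder for unit tests (fast, untrained).
fx_tiny_model <- function() fx("tiny_model", {
  v <- fx_vocab()
  cfg <- encoder_config(vocab_size = vocab_size(v), n_layers = 1L, n_heads = 2L,
                        hidden_size = 16L, ff_size = 32L, max_len = 160L,
                        seed = 7)
  init_model(cfg, vocab = v)
})

# A quickly trained multiclass task model (frozen encoder, head only) for
# tests that need predictions but not predictive skill.
fx_task_model <- function() fx("task_model", {
  corp <- fx_corpus()
  sp <- stratified_split(corp$records, c(6, 2, 2), seed = 9)
  finetune(fx_tiny_model(), sp$train, sp$val, head_config("multiclass4"),
           train_config(finetune_epochs = 2, seed = 3), freeze_encoder = TRUE)
})

fx_split <- function() fx("split", stratified_split(fx_corpus()$records, c(6, 2, 2), seed = 9))

expect_bitwise_equal <- function(a, b) {
  expect_identical(lapply(a, unname), lapply(b, unname))
}
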