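# Two-stage pretraining and fine-tuning behaviour on toy profiles.

tiny_cfg <- function(v, seed = 3) {
  encoder_config(vocab_size = vocab_size(v), n_layers = 1, n_heads = 2,
                 hidden_size = 32, ff_size = 64, max_len = 160, seed = seed)
}

test_that("zero pretraining epochs leave the parameters bitwise unchanged", {
  v <- fx_vocab()
  model <- init_model(tiny_cfg(v), vocab = v)
  before <- model$params
  res <- pretrain_stage1(model, fx_corpus()$records[1:10, ],
                         train_config(stage1_epochs = 0, seed = 1))
  expect_identical(res$model$params, before)
  expect_identical(nrow(res$trace), 0L)
})

test_that("stage-1 pretraining reduces the MLM loss on a toy corpus", {
  corp <- fx_corpus()
  recs <- corp$records[1:60, ]
  v <- fx_vocab()
  model <- init_model(tiny_cfg(v, seed = 7), vocab = v)
  res <- pretrain_stage1(model, recs,
                         train_config(stage1_epochs = 3, batch_size = 8, seed = 7))
  tr <- res$trace
  expect_lt(mean(tr$mlm[tr$epoch == 3]), mean(tr$mlm[tr$epoch == 1]))
  # bookkeeping: epochs x batches rows
  expect_identical(nrow(tr), as.integer(3 * ceiling(60 / 8)))
  expect_identical(res$model$stage, "stage1")
})

test_that("stage 2 requires a stage-1 model unless cold-started", {
  corp <- fx_corpus()
  v <- fx_vocab()
  model <- init_model(tiny_cfg(v), vocab = v)
  expect_error(pretrain_stage2(model, corp$records[1:8, ], corp$catalog,
                               train_config(stage2_epochs = 1, seed = 1)),
               class = "rxy_config_error")
  expect_no_error(pretrain_stage2(model, corp$records[1:8, ], corp$catalog,
                                  train_config(stage2_epochs = 1, seed = 1),
                                  cold_start = TRUE))
})

test_that("with the contrastive weight at zero the combined loss is pure MLM", {
  corp <- fx_corpus()
  v <- fx_vocab()
  model <- init_model(tiny_cfg(v), vocab = v)
  res <- pretrain_stage2(model, corp$records[1:16, ], corp$catalog,
                         train_config(stage2_epochs = 1, cl_weight = 0, seed = 5),
                         cold_start = TRUE)
  expect_equal(res$trace$total, res$trace$mlm)
  expect_true(all(res$trace$cl == 0))
})

test_that("stage 2 drives anchor-negative cosines down over epochs", {
  corp <- fx_corpus()
  recs <- corp$records[1:40, ]
  v <- fx_vocab()
  model <- init_model(tiny_cfg(v, seed = 2), vocab = v)
  invisible(pretrain_stage1(model, recs, train_config(stage1_epochs = 1, seed = 2)))
  res <- pretrain_stage2(model, recs, corp$catalog,
                         train_config(stage2_epochs = 3, batch_size = 8,
                                      lr = 2e-3, seed = 2))
  tr <- res$trace
  expect_lt(mean(tr$neg_cos[tr$epoch == 3]), mean(tr$neg_cos[tr$epoch == 1]))
})

test_that("pretraining runs are reproducible from their seed", {
  corp <- fx_corpus()
  recs <- corp$records[1:12, ]
  v <- fx_vocab()
  run <- function() {
    m <- init_model(tiny_cfg(v, seed = 4), vocab = v)
    r1 <- pretrain_stage1(m, recs, train_config(stage1_epochs = 1, seed = 4))
    r2 <- pretrain_stage2(m, recs, corp$catalog,
                          train_config(stage2_epochs = 1, seed = 4))
    list(p = m$params, t1 = r1$trace, t2 = r2$trace)
  }
  a <- run(); b <- run()
  expect_identical(a$p, b$p)
  expect_identical(a$t1, b$t1)
  expect_identical(a$t2, b$t2)
})

test_that("regression fine-tuning on a constant-yield set converges to it", {
  recs <- fx_corpus()$records[1:20, ]
  recs$yield_percent <- 70
  model <- fx_tiny_model()
  task <- finetune(model, recs, head_cfg = head_config("regression"),
                   cfg = train_config(finetune_epochs = 40, lr = 5e-3, seed = 6),
                   freeze_encoder = TRUE)
  pred <- predict_yields(task, recs)
  expect_true(all(abs(pred$yield_fraction - 0.7) < 0.02))
})

test_that("freezing the encoder leaves its weights bitwise unchanged", {
  model <- fx_tiny_model()
  before <- model$params
  sp <- fx_split()
  task <- finetune(model, sp$train[1:16, ], sp$val[1:8, ],
                   head_config("multiclass4"),
                   train_config(finetune_epochs = 1, seed = 2),
                   freeze_encoder = TRUE)
  expect_identical(task$encoder$params, before)
  # and the source model is never mutated by fine-tuning
  task2 <- finetune(model, sp$train[1:16, ], sp$val[1:8, ],
                    head_config("multiclass4"),
                    train_config(finetune_epochs = 1, seed = 2))
  expect_identical(model$params, before)
})

test_that("fine-tuning rejects records without usable labels", {
  recs <- fx_corpus()$records[1:4, ]
  recs$yield_percent[2] <- NA
  expect_error(finetune(fx_tiny_model(), recs,
                        head_cfg = head_config("multiclass4"),
                        cfg = train_config(finetune_epochs = 1, seed = 1)),
               class = "rxy_config_error")
})

test_that("head outputs are proper probabilities and clamped yields", {
  model <- fx_tiny_model()
  emb <- encode(model, fx_corpus()$records$reaction_smiles[1:5])
  probs <- predict_head(model, emb, head_config("multiclass4"))
  expect_equal(unname(rowSums(probs)), rep(1, 5), tolerance = 1e-6)
  expect_true(all(probs >= 0))
  reg <- predict_head(model, emb, head_config("regression"))
  expect_true(all(reg >= 0 & reg <= 1))
  expect_error(predict_head(model, emb[, 1:5], head_config("regression")),
               class = "rxy_shape_error")
})

test_that("prediction is aligned, deterministic, and failure-aware", {
  task <- fx_task_model()
  recs <- fx_corpus()$records[1:6, ]
  p1 <- predict_yields(task, recs)
  expect_identical(p1$record_id, recs$record_id)
  expect_identical(predict_yields(task, recs), p1)
  perm <- c(4, 2, 6, 1, 3, 5)
  p2 <- predict_yields(task, recs[perm, ])
  expect_identical(p2$record_id, recs$record_id[perm])
  expect_equal(p2$pred_bin, p1$pred_bin[perm])

  recs_bad <- recs
  recs_bad$reaction_smiles[3] <- "CCX>O>CC"
  expect_warning(p3 <- predict_yields(task, recs_bad), class = "rxy_warning")
  expect_identical(nrow(p3), 5L)
  expect_length(attr(p3, "failures"), 1L)
})
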