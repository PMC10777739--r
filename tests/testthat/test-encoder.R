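# Transformer encoder: shapes, determinism, masking, backprop, checkpoints.

test_that("configuration validates head divisibility", {
  expect_no_error(encoder_config(vocab_size = 30, hidden_size = 256, n_heads = 4))
  expect_error(encoder_config(vocab_size = 30, hidden_size = 250, n_heads = 4),
               class = "rxy_config_error")
})

test_that("initialization is deterministic and the parameter count is exact", {
  v <- fx_vocab()
  cfg <- encoder_config(vocab_size = vocab_size(v), n_layers = 2, n_heads = 4,
                        hidden_size = 64, ff_size = 128, max_len = 100, seed = 3)
  m1 <- init_model(cfg)
  m2 <- init_model(cfg)
  expect_identical(m1$params, m2$params)

  # closed-form count of the declared architecture
  V <- vocab_size(v); d <- 64; f <- 128; L <- 2; maxlen <- 100
  per_layer <- 4 * (d * d + d) +      # attention projections
    2 * 2 * d +                       # two layer norms
    (d * f + f) + (f * d + d)         # feedforward
  expected <- V * d + maxlen * d + L * per_layer +
    (d * d + d) + 2 * d + V           # MLM head (decoder tied to embeddings)
  expect_identical(param_count(m1), as.integer(expected))
})

test_that("encoding is deterministic, padding-invariant, and shape-correct", {
  model <- fx_tiny_model()
  smi <- fx_corpus()$records$reaction_smiles[1:3]
  e1 <- encode(model, smi)
  e2 <- encode(model, smi)
  expect_identical(e1, e2)
  expect_identical(dim(e1), c(3L, model$config$hidden_size))

  ids <- token_sequence(smi[1], model$vocab)$ids
  padded <- c(ids, rep(model$vocab$pad, 10))
  expect_equal(encode(model, list(ids)), encode(model, list(padded)),
               tolerance = 1e-12)

  long <- paste0(strrep("C", 200), ">O>", strrep("C", 200))
  expect_error(encode(model, long), class = "rxy_length_error")
})

test_that("changing one condition token moves the embedding", {
  model <- fx_tiny_model()
  corp <- fx_corpus()
  a <- corp$records$reaction_smiles[1]
  negs <- make_negatives(a, corp$catalog, k = 1, seed = 4)
  d <- sqrt(sum((encode(model, a) - encode(model, negs))^2))
  expect_gt(d, 0)
})

test_that("mlm_logits returns one finite score vector per masked position", {
  model <- fx_tiny_model()
  seq <- token_sequence(fx_corpus()$records$reaction_smiles[1], model$vocab)
  m <- mask_tokens(seq, model$vocab, 0.3, seed = 1)
  lg <- mlm_logits(model, m)
  expect_identical(dim(lg), c(length(m$positions), model$config$vocab_size))
  expect_true(all(is.finite(lg)))
})

test_that("encoder and head gradients match finite differences", {
  v <- build_vocabulary(c("CCO>[Pd]>CCO", "CC(=O)O>O>CCO"))
  cfg <- encoder_config(vocab_size = vocab_size(v), n_layers = 2, n_heads = 2,
                        hidden_size = 8, ff_size = 16, max_len = 32, seed = 3)
  model <- init_model(cfg, vocab = v)
  seq <- token_sequence("CC(=O)O>O>CCO", v)
  masked <- mask_tokens(seq, v, 0.3, seed = 5)
  target <- sin(seq_len(8))

  loss_fn <- function(params) {
    fw <- rxnyield:::encoder_forward(params, cfg, masked$ids, keep_cache = FALSE)
    hd <- rxnyield:::mlm_head_forward(params, fw$X, masked$positions)
    mlm_loss(hd$logits, masked) + 0.1 * cosine_similarity(fw$X[1, ], target)
  }
  p <- model$params
  fw <- rxnyield:::encoder_forward(p, cfg, masked$ids, train = TRUE)
  hd <- rxnyield:::mlm_head_forward(p, fw$X, masked$positions)
  dlog <- rxnyield:::mlm_loss_grad(hd$logits, masked$labels)
  hb <- rxnyield:::mlm_head_backward(p, hd, dlog, masked$positions, length(masked$ids))
  dX <- hb$dX
  dX[1, ] <- dX[1, ] + 0.1 * rxnyield:::.cos_grad_a(fw$X[1, ], target)
  g <- rxnyield:::encoder_backward(p, cfg, fw, dX)
  g <- rxnyield:::acc_grads(g, hb$grads)
  g$emb_tok <- g$emb_tok + hb$dE_dec

  eps <- 1e-5
  set.seed(9)
  for (nm in c("emb_tok", "L1_Wq", "L1_Wo", "L1_ln1_g", "L1_W1", "L2_W2",
               "L2_ln2_b", "mlm_W", "mlm_dec_b")) {
    for (ii in sample(length(p[[nm]]), 3)) {
      p1 <- p; p1[[nm]][ii] <- p1[[nm]][ii] + eps
      p2 <- p; p2[[nm]][ii] <- p2[[nm]][ii] - eps
      num <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
      ana <- g[[nm]][ii]
      if (abs(num) + abs(ana) > 1e-7) {
        expect_equal(ana, num, tolerance = 1e-3)
      }
    }
  }
})

test_that("an overfit model recovers the masked tokens", {
  v <- build_vocabulary("CC(=O)Cl.CCO>CCN(CC)CC>CCOC(C)=O")
  cfg <- encoder_config(vocab_size = vocab_size(v), n_layers = 1, n_heads = 2,
                        hidden_size = 32, ff_size = 64, max_len = 64, seed = 4)
  model <- init_model(cfg, vocab = v)
  seq <- token_sequence("CC(=O)Cl.CCO>CCN(CC)CC>CCOC(C)=O", v)
  masked <- mask_tokens(seq, v, 0.2, seed = 8)
  params <- model$params
  state <- rxnyield:::adam_state(params)
  for (step in 1:200) {
    ps <- rxnyield:::.mlm_pass(params, cfg, masked)
    upd <- rxnyield:::adam_step(params, ps$grads, state, 1e-3)
    params <- upd$params; state <- upd$state
  }
  model$params <- params
  lg <- mlm_logits(model, masked)
  expect_identical(unname(apply(lg, 1, which.max)), as.integer(masked$labels))
})

test_that("checkpoints round-trip bitwise and reject garbage", {
  model <- fx_tiny_model()
  p <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(model, p)
  back <- load_checkpoint(p)
  expect_identical(back$params, model$params)
  expect_identical(back$config, model$config)
  expect_identical(back$vocab, model$vocab)
  smi <- fx_corpus()$records$reaction_smiles[1:2]
  expect_identical(encode(back, smi), encode(model, smi))

  bad <- withr::local_tempfile(fileext = ".ckpt")
  writeLines("not a checkpoint", bad)
  expect_error(load_checkpoint(bad), class = "rxy_checkpoint_error")
})
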