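# Two-stage pretraining and task fine-tuning.
#
# Stage 1 optimizes the MLM objective alone; stage 2 optimizes the exact sum
# of the MLM cross-entropy and the condition-contrastive loss on every
# batch. Fine-tuning initializes the encoder from a pretraining checkpoint
# and trains a feedforward head (regression or 4-class) with
# validation-based checkpoint selection. All loops are single-threaded and
# deterministic given the config seed.

#' Training configuration
#'
#' Stage epoch defaults (50 MLM-only, then 10 combined) match the full-scale
#' schedule; tests use toy profiles.
#'
#' @param stage1_epochs,stage2_epochs,finetune_epochs Epoch counts.
#' @param batch_size Sequences (stage 1) or anchors (stage 2) per update.
#' @param lr Adam learning rate.
#' @param warmup Linear warmup steps.
#' @param mask_rate MLM masking rate.
#' @param n_pos,n_neg Positives / negatives per anchor in stage 2.
#' @param cl_weight Weight on the contrastive term in stage 2 (0 trains an
#'   MLM-only twin on an identical schedule).
#' @param seed Integer seed.
#' @return List of class `rxy_train_config`.
#' @export
train_config <- function(stage1_epochs = 50L, stage2_epochs = 10L,
                         finetune_epochs = 10L, batch_size = 8L, lr = 1e-3,
                         warmup = 10L, mask_rate = 0.15, n_pos = 1L,
                         n_neg = 2L, cl_weight = 1, seed = 1L) {
  cfg <- list(stage1_epochs = as.integer(stage1_epochs),
              stage2_epochs = as.integer(stage2_epochs),
              finetune_epochs = as.integer(finetune_epochs),
              batch_size = as.integer(batch_size), lr = as.numeric(lr),
              warmup = as.integer(warmup), mask_rate = as.numeric(mask_rate),
              n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
              cl_weight = as.numeric(cl_weight), seed = as.integer(seed))
  if (any(c(cfg$stage1_epochs, cfg$stage2_epochs, cfg$finetune_epochs) < 0L) ||
      cfg$batch_size < 1L || cfg$lr <= 0 || cfg$mask_rate < 0 || cfg$mask_rate > 1) {
    rxy_abort("rxy_config_error", "invalid training configuration")
  }
  class(cfg) <- "rxy_train_config"
  cfg
}

.records_smiles <- function(corpus) {
  if (is.data.frame(corpus)) corpus$reaction_smiles else as.character(corpus)
}

# Pre-tokenize a corpus once; warns about out-of-vocabulary tokens (they map
# to [UNK]).
.prep_sequences <- function(smiles, vocab) {
  seqs <- lapply(smiles, token_sequence, vocab = vocab)
  n_unk <- sum(vapply(seqs, function(s) sum(s$ids == vocab$unk), 1L))
  if (n_unk > 0L) {
    rxy_warn(sprintf("%d token occurrence(s) outside the vocabulary mapped to [UNK]", n_unk))
  }
  seqs
}

# One MLM forward/backward for a masked sequence; returns loss and grads.
.mlm_pass <- function(params, cfg, masked) {
  fw <- encoder_forward(params, cfg, masked$ids, train = TRUE)
  hd <- mlm_head_forward(params, fw$X, masked$positions)
  loss <- mlm_loss(hd$logits, masked)
  dlog <- mlm_loss_grad(hd$logits, masked$labels)
  hb <- mlm_head_backward(params, hd, dlog, masked$positions, length(masked$ids))
  g <- encoder_backward(params, cfg, fw, hb$dX)
  g <- acc_grads(g, hb$grads)
  g$emb_tok <- g$emb_tok + hb$dE_dec
  list(loss = loss, grads = g)
}

#' Stage-1 pretraining: masked language modeling only
#'
#' @param model An `rxy_model` with an attached vocabulary built from the
#'   corpus.
#' @param corpus Reaction record data.frame or character vector of reaction
#'   SMILES.
#' @param cfg A [train_config()].
#' @return List with the trained `model` (also updated in place) and a
#'   per-batch loss `trace` data.frame.
#' @export
pretrain_stage1 <- function(model, corpus, cfg = train_config()) {
  stopifnot(inherits(model, "rxy_model"), inherits(cfg, "rxy_train_config"))
  if (is.null(model$vocab)) {
    rxy_abort("rxy_config_error", "model needs an attached vocabulary for pretraining")
  }
  smiles <- .records_smiles(corpus)
  seqs <- .prep_sequences(smiles, model$vocab)
  trace <- list()
  if (cfg$stage1_epochs > 0L) {
    params <- model$params
    state <- adam_state(params)
    step <- 0L
    for (epoch in seq_len(cfg$stage1_epochs)) {
      ord <- with_local_seed(derive_seed(cfg$seed, paste0("s1_shuffle_", epoch)),
                             sample.int(length(seqs)))
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      for (b in seq_along(batches)) {
        idx <- batches[[b]]
        grads <- list(); loss_sum <- 0; n_used <- 0L
        for (j in idx) {
          step <- step + 1L
          masked <- mask_tokens(seqs[[j]], model$vocab, cfg$mask_rate,
                                seed = derive_seed(cfg$seed, paste0("s1_mask_", step)))
          if (length(masked$positions) == 0L) next
          ps <- .mlm_pass(params, model$config, masked)
          grads <- acc_grads(grads, ps$grads)
          loss_sum <- loss_sum + ps$loss
          n_used <- n_used + 1L
        }
        if (n_used == 0L) next
        grads <- lapply(grads, function(g) g / n_used)
        upd <- adam_step(params, grads, state, cfg$lr, warmup = cfg$warmup)
        params <- upd$params; state <- upd$state
        trace[[length(trace) + 1L]] <-
          data.frame(stage = 1L, epoch = epoch, batch = b,
                     mlm = loss_sum / n_used, cl = NA_real_,
                     total = loss_sum / n_used)
      }
    }
    model$params <- params
    model$stage <- "stage1"
  }
  list(model = model,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(stage = integer(0), epoch = integer(0), batch = integer(0),
                    mlm = numeric(0), cl = numeric(0), total = numeric(0)))
}

#' Stage-2 pretraining: MLM plus condition-contrastive learning
#'
#' Each batch optimizes `mean-MLM + cl_weight * CLloss`. Anchor embeddings
#' for the contrastive term come from a clean (unmasked) forward pass of the
#' canonical reaction; positives and negatives are rebuilt every epoch from
#' an epoch-derived seed. The trace reports both loss components plus the
#' mean anchor-negative and anchor-positive cosines per batch.
#'
#' @param model A stage-1 pretrained `rxy_model` (or any model with
#'   `cold_start = TRUE`).
#' @param records Reaction record data.frame (canonical SMILES).
#' @param catalog Role-keyed condition catalog for negative generation.
#' @param cfg A [train_config()].
#' @param loss_cfg A [loss_config()].
#' @param cold_start Allow starting from a model that has not completed
#'   stage 1.
#' @return List with the trained `model` and the `trace` data.frame.
#' @export
pretrain_stage2 <- function(model, records, catalog, cfg = train_config(),
                            loss_cfg = loss_config(), cold_start = FALSE) {
  stopifnot(inherits(model, "rxy_model"))
  if (!identical(model$stage, "stage1") && !cold_start) {
    rxy_abort("rxy_config_error",
              "stage-2 pretraining expects a stage-1 model (or cold_start = TRUE)")
  }
  if (is.null(model$vocab)) {
    rxy_abort("rxy_config_error", "model needs an attached vocabulary for pretraining")
  }
  trace <- list()
  params <- model$params
  state <- adam_state(params)
  step <- 0L
  for (epoch in seq_len(cfg$stage2_epochs)) {
    triplets <- suppressWarnings(
      build_contrastive_batch(records, catalog, n_pos = cfg$n_pos,
                              n_neg = cfg$n_neg,
                              seed = derive_seed(cfg$seed, paste0("s2_aug_", epoch))))
    ord <- with_local_seed(derive_seed(cfg$seed, paste0("s2_shuffle_", epoch)),
                           sample.int(length(triplets)))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    for (b in seq_along(batches)) {
      idx <- batches[[b]]
      grads <- list(); mlm_sum <- 0; n_used <- 0L
      fws <- list(); emb_batch <- list()
      for (j in idx) {
        tr <- triplets[[j]]
        step <- step + 1L
        # MLM pass on the masked anchor
        aseq <- token_sequence(tr$anchor, model$vocab)
        masked <- mask_tokens(aseq, model$vocab, cfg$mask_rate,
                              seed = derive_seed(cfg$seed, paste0("s2_mask_", step)))
        if (length(masked$positions) > 0L) {
          ps <- .mlm_pass(params, model$config, masked)
          grads <- acc_grads(grads, lapply(ps$grads, function(g) g)) # accumulate
          mlm_sum <- mlm_sum + ps$loss
          n_used <- n_used + 1L
        }
        if (cfg$cl_weight > 0) {
          # clean passes for the contrastive term
          fw_a <- encoder_forward(params, model$config, aseq$ids, train = TRUE)
          fw_p <- lapply(tr$positives, function(s)
            encoder_forward(params, model$config, token_sequence(s, model$vocab)$ids, train = TRUE))
          fw_n <- lapply(tr$negatives, function(s)
            encoder_forward(params, model$config, token_sequence(s, model$vocab)$ids, train = TRUE))
          fws[[length(fws) + 1L]] <- list(a = fw_a, p = fw_p, n = fw_n)
          emb_batch[[length(emb_batch) + 1L]] <-
            list(anchor = fw_a$X[1L, ],
                 positives = lapply(fw_p, function(f) f$X[1L, ]),
                 negatives = lapply(fw_n, function(f) f$X[1L, ]))
        }
      }
      if (n_used > 0L) {
        # mean-MLM scaling to match stage 1
        for (nm in names(grads)) grads[[nm]] <- grads[[nm]] / n_used
      }
      cl_val <- 0; neg_cos <- NA_real_; pos_cos <- NA_real_
      if (cfg$cl_weight > 0 && length(emb_batch) > 0L) {
        cl_val <- contrastive_loss(emb_batch, loss_cfg)
        cgr <- contrastive_loss_grads(emb_batch, loss_cfg)
        for (q in seq_along(fws)) {
          gset <- cgr[[q]]; fset <- fws[[q]]
          back_one <- function(fw, dvec) {
            dX <- matrix(0, length(fw$ids), model$config$hidden_size)
            dX[1L, ] <- dvec * cfg$cl_weight
            encoder_backward(params, model$config, fw, dX)
          }
          grads <- acc_grads(grads, back_one(fset$a, gset$anchor))
          for (t in seq_along(fset$p)) grads <- acc_grads(grads, back_one(fset$p[[t]], gset$positives[[t]]))
          for (t in seq_along(fset$n)) grads <- acc_grads(grads, back_one(fset$n[[t]], gset$negatives[[t]]))
        }
        neg_cos <- mean(unlist(lapply(emb_batch, function(e)
          vapply(e$negatives, cosine_similarity, 0, va = e$anchor))))
        pos_cos <- mean(unlist(lapply(emb_batch, function(e)
          vapply(e$positives, cosine_similarity, 0, va = e$anchor))))
      }
      if (length(grads) == 0L) next
      upd <- adam_step(params, grads, state, cfg$lr, warmup = cfg$warmup)
      params <- upd$params; state <- upd$state
      mlm_mean <- if (n_used > 0L) mlm_sum / n_used else NA_real_
      trace[[length(trace) + 1L]] <-
        data.frame(stage = 2L, epoch = epoch, batch = b, mlm = mlm_mean,
                   cl = cl_val,
                   total = (if (is.na(mlm_mean)) 0 else mlm_mean) + cfg$cl_weight * cl_val,
                   neg_cos = neg_cos, pos_cos = pos_cos)
    }
  }
  if (cfg$stage2_epochs > 0L) {
    model$params <- params
    model$stage <- "stage2"
  }
  list(model = model,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(stage = integer(0), epoch = integer(0), batch = integer(0),
                    mlm = numeric(0), cl = numeric(0), total = numeric(0),
                    neg_cos = numeric(0), pos_cos = numeric(0)))
}

.task_labels <- function(records, kind) {
  if (any(is.na(records$yield_percent))) {
    rxy_abort("rxy_config_error", "records must carry yields for fine-tuning")
  }
  if (kind == "regression") {
    records$yield_percent / 100
  } else {
    as.integer(bin_yield(records$yield_percent))
  }
}

# Loss gradient at the head output pre-activations.
.task_dZ2 <- function(kind, cache, y) {
  n <- nrow(cache$Z2)
  if (kind == "regression") {
    out <- cache$out
    (2 / n) * (out - y) * out * (1 - out)
  } else {
    P <- exp(log_softmax_rows(cache$Z2))
    P[cbind(seq_len(n), y)] <- P[cbind(seq_len(n), y)] - 1
    P / n
  }
}

.task_loss <- function(kind, out, y) {
  if (kind == "regression") {
    mean((as.numeric(out) - y)^2)
  } else {
    -mean(log(pmax(out[cbind(seq_along(y), y)], 1e-12)))
  }
}

#' Fine-tune a pretrained encoder on a yield prediction task
#'
#' Loads the pretrained encoder weights, trains a feedforward head (and,
#' unless frozen, the encoder) on the training records, and keeps the
#' parameters of the epoch with the lowest validation loss.
#'
#' @param model A pretrained `rxy_model` (left unmodified; weights are
#'   copied).
#' @param train_records,val_records Reaction record data.frames with yields.
#' @param head_cfg A [head_config()].
#' @param cfg A [train_config()] (`finetune_epochs`, `batch_size`, `lr`,
#'   `seed` are used).
#' @param freeze_encoder If TRUE only the head is trained.
#' @return An `rxy_task_model`: list with `encoder`, `head`, `trace`,
#'   `best_epoch`.
#' @export
finetune <- function(model, train_records, val_records = NULL,
                     head_cfg = head_config(), cfg = train_config(),
                     freeze_encoder = FALSE) {
  stopifnot(inherits(model, "rxy_model"), inherits(head_cfg, "rxy_head_config"))
  kind <- head_cfg$kind
  y_tr <- .task_labels(train_records, kind)
  seqs <- .prep_sequences(train_records$reaction_smiles, model$vocab)
  has_val <- !is.null(val_records) && nrow(val_records) > 0L
  if (has_val) {
    y_va <- .task_labels(val_records, kind)
    seqs_va <- .prep_sequences(val_records$reaction_smiles, model$vocab)
  }

  enc_params <- model$params
  head_params <- init_head(head_cfg, model$config$hidden_size,
                           seed = derive_seed(cfg$seed, "head_init"))
  all_params <- c(enc_params, stats::setNames(head_params, paste0("head_", names(head_params))))
  state <- adam_state(all_params)
  best <- list(loss = Inf, params = all_params, epoch = 0L)
  trace <- list()

  eval_loss <- function(params) {
    if (!has_val) return(NA_real_)
    emb <- matrix(0, length(seqs_va), model$config$hidden_size)
    for (i in seq_along(seqs_va)) {
      emb[i, ] <- encoder_forward(params, model$config, seqs_va[[i]]$ids,
                                  keep_cache = FALSE)$X[1L, ]
    }
    hp <- list(W1 = params$head_W1, b1 = params$head_b1,
               W2 = params$head_W2, b2 = params$head_b2)
    .task_loss(kind, head_forward(hp, head_cfg, emb)$out, y_va)
  }

  for (epoch in seq_len(cfg$finetune_epochs)) {
    ord <- with_local_seed(derive_seed(cfg$seed, paste0("ft_shuffle_", epoch)),
                           sample.int(length(seqs)))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0; nb <- 0L
    for (idx in batches) {
      fws <- lapply(idx, function(j)
        encoder_forward(all_params, model$config, seqs[[j]]$ids,
                        train = !freeze_encoder, keep_cache = !freeze_encoder))
      emb <- do.call(rbind, lapply(fws, function(f) f$X[1L, , drop = FALSE]))
      hp <- list(W1 = all_params$head_W1, b1 = all_params$head_b1,
                 W2 = all_params$head_W2, b2 = all_params$head_b2)
      hf <- head_forward(hp, head_cfg, emb, train = TRUE)
      yb <- if (kind == "regression") y_tr[idx] else y_tr[idx]
      loss <- .task_loss(kind, hf$out, yb)
      dZ2 <- .task_dZ2(kind, hf, yb)
      hb <- head_backward(hp, head_cfg, hf, dZ2)
      grads <- stats::setNames(hb$grads, paste0("head_", names(hb$grads)))
      if (!freeze_encoder) {
        for (q in seq_along(fws)) {
          dX <- matrix(0, length(fws[[q]]$ids), model$config$hidden_size)
          dX[1L, ] <- hb$demb[q, ]
          grads <- acc_grads(grads, encoder_backward(all_params, model$config,
                                                     fws[[q]], dX))
        }
      }
      upd <- adam_step(all_params, grads, state, cfg$lr, warmup = cfg$warmup)
      all_params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    vl <- eval_loss(all_params)
    trace[[length(trace) + 1L]] <-
      data.frame(epoch = epoch, train_loss = ep_loss / max(nb, 1L), val_loss = vl)
    sel <- if (has_val) vl else ep_loss / max(nb, 1L)
    if (!is.na(sel) && sel < best$loss) {
      best <- list(loss = sel, params = all_params, epoch = epoch)
    }
  }
  final <- if (cfg$finetune_epochs > 0L) best$params else all_params

  enc <- clone_model(model)
  enc$params <- final[names(enc_params)]
  enc$stage <- paste0(model$stage, "+finetuned")
  task <- list(encoder = enc,
               head = list(params = list(W1 = final$head_W1, b1 = final$head_b1,
                                         W2 = final$head_W2, b2 = final$head_b2),
                           config = head_cfg),
               trace = if (length(trace)) do.call(rbind, trace) else NULL,
               best_epoch = best$epoch)
  class(task) <- "rxy_task_model"
  task
}

#' @export
print.rxy_task_model <- function(x, ...) {
  cat(sprintf("<rxy_task_model: %s head on %s encoder>\n",
              x$head$config$kind, x$encoder$stage))
  invisible(x)
}

#' Predict yields for reaction records
#'
#' Deterministic, order-preserving batch prediction. Records whose SMILES
#' fail tokenization are reported (warning + `failures` attribute) and
#' excluded from the output.
#'
#' @param task_model An `rxy_task_model` from [finetune()].
#' @param records Reaction record data.frame (or character vector of
#'   reaction SMILES).
#' @return data.frame with `record_id` and either `yield_fraction`
#'   (regression) or the four class-probability columns plus `pred_bin`.
#' @export
predict_yields <- function(task_model, records) {
  stopifnot(inherits(task_model, "rxy_task_model"))
  if (!is.data.frame(records)) {
    records <- data.frame(record_id = sprintf("R%06d", seq_along(records)),
                          reaction_smiles = as.character(records),
                          stringsAsFactors = FALSE)
  }
  model <- task_model$encoder
  ok <- logical(nrow(records))
  seqs <- vector("list", nrow(records))
  fail_msgs <- character(0)
  for (i in seq_len(nrow(records))) {
    s <- tryCatch(token_sequence(records$reaction_smiles[i], model$vocab),
                  rxy_error = function(e) e)
    if (inherits(s, "condition")) {
      fail_msgs <- c(fail_msgs, sprintf("%s: %s", records$record_id[i],
                                        conditionMessage(s)))
    } else {
      ok[i] <- TRUE
      seqs[[i]] <- s
    }
  }
  if (length(fail_msgs)) {
    rxy_warn(sprintf("%d record(s) failed tokenization and were skipped", length(fail_msgs)))
  }
  emb <- matrix(0, sum(ok), model$config$hidden_size)
  kidx <- which(ok)
  for (q in seq_along(kidx)) {
    emb[q, ] <- encoder_forward(model$params, model$config, seqs[[kidx[q]]]$ids,
                                keep_cache = FALSE)$X[1L, ]
  }
  out <- predict_head(model, emb, task_model$head)
  res <- if (task_model$head$config$kind == "regression") {
    data.frame(record_id = records$record_id[ok], yield_fraction = out,
               stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(out)
    df$pred_bin <- factor(YIELD_BIN_LEVELS[max.col(out)], levels = YIELD_BIN_LEVELS,
                          ordered = TRUE)
    cbind(data.frame(record_id = records$record_id[ok], stringsAsFactors = FALSE), df)
  }
  attr(res, "failures") <- fail_msgs
  res
}
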