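# Episodic meta-learning over reaction categories.
#
# Categories with abundant data serve as meta-training tasks; low-data
# categories are held out as meta-test tasks. The meta-learner is a
# first-order initialization learner (Reptile): each episode adapts a clone
# of the current initialization on one task's support set for a few inner
# steps, then moves the initialization toward the adapted weights. At
# meta-test time the learned initialization is adapted on the small support
# set of an unseen category and evaluated once on its test records.

#' Meta-learning configuration
#'
#' The default category layout assigns the seven data-rich reaction classes
#' (heteroatom alkylation/arylation 1, acylation 2, C-C bond formation 3,
#' heterocycle formation 4, protections 5, reductions 7, oxidations 8) to
#' meta-training and the five low-data / low-quality classes (unrecognized
#' 0, deprotections 6, functional group interconversion 9, functional group
#' addition 10, resolutions 11) to meta-testing.
#'
#' @param train_categories,test_categories Disjoint integer category sets.
#' @param episodes Number of meta-training episodes.
#' @param inner_steps Adaptation steps per episode (and at meta-test).
#' @param inner_lr Adam learning rate for inner adaptation.
#' @param outer_lr Reptile interpolation step toward adapted weights.
#' @param support_batch Records per inner step.
#' @param seed Integer seed.
#' @return List of class `rxy_meta_config`.
#' @export
meta_config <- function(train_categories = c(1L, 2L, 3L, 4L, 5L, 7L, 8L),
                        test_categories = c(0L, 6L, 9L, 10L, 11L),
                        episodes = 60L, inner_steps = 6L, inner_lr = 2e-3,
                        outer_lr = 0.5, support_batch = 8L, seed = 1L) {
  cfg <- list(train_categories = as.integer(train_categories),
              test_categories = as.integer(test_categories),
              episodes = as.integer(episodes),
              inner_steps = as.integer(inner_steps),
              inner_lr = as.numeric(inner_lr), outer_lr = as.numeric(outer_lr),
              support_batch = as.integer(support_batch), seed = as.integer(seed))
  if (length(intersect(cfg$train_categories, cfg$test_categories)) > 0L) {
    rxy_abort("rxy_config_error", "meta train/test category sets must be disjoint")
  }
  if (cfg$episodes < 0L || cfg$inner_steps < 0L || cfg$outer_lr < 0) {
    rxy_abort("rxy_config_error", "invalid meta-learning configuration")
  }
  class(cfg) <- "rxy_meta_config"
  cfg
}

#' Build per-category meta-tasks from split records
#'
#' Supports come from the training split, queries from the validation
#' split, and (for meta-test tasks) evaluation records from the test split.
#'
#' @param splits List of record data.frames `train`, `val`, `test` (as from
#'   [stratified_split()]), each carrying category ids.
#' @param cfg A [meta_config()].
#' @return List with `train` and `test` lists of `rxy_meta_task` objects.
#' @export
build_meta_tasks <- function(splits, cfg = meta_config()) {
  stopifnot(inherits(cfg, "rxy_meta_config"))
  mk <- function(cat, with_test) {
    support <- splits$train[!is.na(splits$train$category_id) &
                              splits$train$category_id == cat, , drop = FALSE]
    if (nrow(support) == 0L) {
      rxy_abort("rxy_task_build_error",
                sprintf("category %d has an empty support set", cat))
    }
    query <- splits$val[!is.na(splits$val$category_id) &
                          splits$val$category_id == cat, , drop = FALSE]
    task <- list(category_id = cat, support = support, query = query,
                 test = if (with_test)
                   splits$test[!is.na(splits$test$category_id) &
                                 splits$test$category_id == cat, , drop = FALSE]
                 else NULL)
    class(task) <- "rxy_meta_task"
    task
  }
  list(train = lapply(cfg$train_categories, mk, with_test = FALSE),
       test = lapply(cfg$test_categories, mk, with_test = TRUE))
}

# Joint (encoder + head) parameter list of a task model.
.joint_params <- function(task_model) {
  c(task_model$encoder$params,
    stats::setNames(task_model$head$params, paste0("head_", names(task_model$head$params))))
}

.split_joint <- function(task_model, params) {
  enc_names <- names(task_model$encoder$params)
  enc <- clone_model(task_model$encoder)
  enc$params <- params[enc_names]
  list(encoder = enc,
       head = list(params = list(W1 = params$head_W1, b1 = params$head_b1,
                                 W2 = params$head_W2, b2 = params$head_b2),
                   config = task_model$head$config))
}

# A few supervised inner steps on support records; returns updated joint
# params. Sequences are pre-tokenized by the caller.
.inner_adapt <- function(params, enc_cfg, head_cfg, seqs, labels, kind,
                         steps, lr, batch, seed) {
  if (steps == 0L) return(params)
  state <- adam_state(params)
  n <- length(seqs)
  for (s in seq_len(steps)) {
    idx <- with_local_seed(derive_seed(seed, paste0("inner_", s)),
                           sample.int(n, min(batch, n)))
    fws <- lapply(idx, function(j)
      encoder_forward(params, enc_cfg, seqs[[j]]$ids, train = TRUE))
    emb <- do.call(rbind, lapply(fws, function(f) f$X[1L, , drop = FALSE]))
    hp <- list(W1 = params$head_W1, b1 = params$head_b1,
               W2 = params$head_W2, b2 = params$head_b2)
    hf <- head_forward(hp, head_cfg, emb, train = TRUE)
    dZ2 <- .task_dZ2(kind, hf, labels[idx])
    hb <- head_backward(hp, head_cfg, hf, dZ2)
    grads <- stats::setNames(hb$grads, paste0("head_", names(hb$grads)))
    for (q in seq_along(fws)) {
      dX <- matrix(0, length(fws[[q]]$ids), enc_cfg$hidden_size)
      dX[1L, ] <- hb$demb[q, ]
      grads <- acc_grads(grads, encoder_backward(params, enc_cfg, fws[[q]], dX))
    }
    upd <- adam_step(params, grads, state, lr)
    params <- upd$params; state <- upd$state
  }
  params
}

#' Meta-train an initialization over the data-rich categories
#'
#' Reptile-style: per episode, one meta-training task is sampled, a clone of
#' the current initialization takes `inner_steps` adaptation steps on the
#' task's support set, and the initialization moves `outer_lr` of the way
#' toward the adapted weights. With 0 episodes or `outer_lr = 0` the model
#' is returned unchanged.
#'
#' @param model A pretrained `rxy_model` (or an `rxy_task_model` to continue
#'   meta-training).
#' @param tasks Meta-training tasks from [build_meta_tasks()].
#' @param cfg A [meta_config()].
#' @param head_cfg Head configuration (default 4-class).
#' @return An `rxy_task_model` holding the meta-learned initialization.
#' @export
meta_train <- function(model, tasks, cfg = meta_config(),
                       head_cfg = head_config("multiclass4")) {
  if (inherits(model, "rxy_model")) {
    task_model <- list(encoder = clone_model(model),
                       head = list(params = init_head(head_cfg, model$config$hidden_size,
                                                      seed = derive_seed(cfg$seed, "meta_head")),
                                   config = head_cfg))
    class(task_model) <- "rxy_task_model"
  } else {
    task_model <- model
    head_cfg <- task_model$head$config
  }
  enc_cfg <- task_model$encoder$config
  vocab <- task_model$encoder$vocab
  kind <- head_cfg$kind

  prep <- lapply(tasks, function(t) {
    list(seqs = suppressWarnings(.prep_sequences(t$support$reaction_smiles, vocab)),
         labels = .task_labels(t$support, kind))
  })

  theta <- .joint_params(task_model)
  for (ep in seq_len(cfg$episodes)) {
    ti <- with_local_seed(derive_seed(cfg$seed, paste0("ep_task_", ep)),
                          sample.int(length(tasks), 1L))
    adapted <- .inner_adapt(theta, enc_cfg, head_cfg,
                            prep[[ti]]$seqs, prep[[ti]]$labels, kind,
                            cfg$inner_steps, cfg$inner_lr, cfg$support_batch,
                            derive_seed(cfg$seed, paste0("ep_", ep)))
    if (cfg$outer_lr > 0) {
      for (nm in names(theta)) {
        theta[[nm]] <- theta[[nm]] + cfg$outer_lr * (adapted[[nm]] - theta[[nm]])
      }
    }
  }
  out <- .split_joint(task_model, theta)
  out$encoder$stage <- paste0(task_model$encoder$stage, "+meta")
  out <- list(encoder = out$encoder, head = out$head,
              meta_config = cfg, trace = NULL, best_epoch = NA_integer_)
  class(out) <- "rxy_task_model"
  out
}

#' Adapt a meta-initialized model on one task and evaluate it
#'
#' Clones the model, runs `inner_steps` adaptation steps on the task's
#' support set, then evaluates once on the task's test records. Reports
#' overall accuracy and per-bin accuracy (recall per true yield class).
#'
#' @param task_model An `rxy_task_model` (typically from [meta_train()]).
#' @param task An `rxy_meta_task` with non-empty support and test sets.
#' @param cfg A [meta_config()].
#' @return List: `category_id`, `accuracy`, `per_bin` (named vector),
#'   `n_test`, `predictions`.
#' @export
meta_adapt_and_eval <- function(task_model, task, cfg = meta_config()) {
  stopifnot(inherits(task_model, "rxy_task_model"), inherits(task, "rxy_meta_task"))
  if (is.null(task$test) || nrow(task$test) == 0L) {
    rxy_abort("rxy_eval_error",
              sprintf("category %d has no test records", task$category_id))
  }
  enc_cfg <- task_model$encoder$config
  head_cfg <- task_model$head$config
  kind <- head_cfg$kind
  vocab <- task_model$encoder$vocab
  seqs <- suppressWarnings(.prep_sequences(task$support$reaction_smiles, vocab))
  labels <- .task_labels(task$support, kind)
  theta <- .inner_adapt(.joint_params(task_model), enc_cfg, head_cfg, seqs,
                        labels, kind, cfg$inner_steps, cfg$inner_lr,
                        cfg$support_batch,
                        derive_seed(cfg$seed, paste0("adapt_", task$category_id)))
  adapted <- .split_joint(task_model, theta)
  adapted <- structure(list(encoder = adapted$encoder, head = adapted$head),
                       class = "rxy_task_model")
  pred <- predict_yields(adapted, task$test)
  truth <- bin_yield(task$test$yield_percent)
  acc <- mean(pred$pred_bin == truth)
  per_bin <- vapply(YIELD_BIN_LEVELS, function(b) {
    sel <- truth == b
    if (!any(sel)) NA_real_ else mean(pred$pred_bin[sel] == b)
  }, 0)
  list(category_id = task$category_id, accuracy = acc, per_bin = per_bin,
       n_test = nrow(task$test), predictions = pred)
}
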