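# BERT-style transformer encoder over reaction token sequences, written on
# base R matrix algebra with hand-derived backpropagation.
#
# Architecture (post-layer-norm, as in the original BERT encoder):
#   X0 = tok_emb[ids] + pos_emb[1:L]
#   per layer: X1 = LN(X + MultiHeadAttention(X)); X2 = LN(X1 + FFN(X1))
#   FFN(x) = W2 gelu(W1 x + c1) + c2
# The reaction embedding is the final hidden vector at the [CLS] position.
# The MLM head is gelu + layer norm + a decoder tied to the token embedding.
#
# Forward passes run one unpadded sequence at a time; [PAD] ids, when
# present, are excluded from attention keys so padding never changes the
# embedding of the real content.

LN_EPS <- 1e-5

#' Encoder configuration
#'
#' Defaults mirror the full-scale model (12 layers, 4 heads, hidden size
#' 256); tests and examples use smaller profiles.
#'
#' @param vocab_size Vocabulary size (including the 5 reserved tokens).
#' @param n_layers,n_heads,hidden_size,ff_size,max_len Architecture sizes;
#'   `hidden_size` must be divisible by `n_heads`.
#' @param dropout Dropout rate on attention/FFN outputs during training.
#' @param seed Initialization seed.
#' @return Object of class `rxy_encoder_config`.
#' @export
encoder_config <- function(vocab_size, n_layers = 12L, n_heads = 4L,
                           hidden_size = 256L, ff_size = 4L * hidden_size,
                           max_len = 512L, dropout = 0, seed = 1L) {
  cfg <- list(vocab_size = as.integer(vocab_size), n_layers = as.integer(n_layers),
              n_heads = as.integer(n_heads), hidden_size = as.integer(hidden_size),
              ff_size = as.integer(ff_size), max_len = as.integer(max_len),
              dropout = as.numeric(dropout), seed = as.integer(seed))
  if (cfg$hidden_size %% cfg$n_heads != 0L) {
    rxy_abort("rxy_config_error",
              sprintf("hidden_size (%d) must be divisible by n_heads (%d)",
                      cfg$hidden_size, cfg$n_heads))
  }
  if (cfg$vocab_size < 6L || cfg$n_layers < 1L || cfg$max_len < 2L ||
      cfg$dropout < 0 || cfg$dropout >= 1) {
    rxy_abort("rxy_config_error", "invalid encoder configuration")
  }
  class(cfg) <- "rxy_encoder_config"
  cfg
}

.layer_param_names <- function(i) {
  paste0("L", i, "_", c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
                        "ln1_g", "ln1_b", "W1", "c1", "W2", "c2",
                        "ln2_g", "ln2_b"))
}

#' Initialize an encoder model
#'
#' Weights are drawn N(0, 0.02), biases zero, layer-norm gains one;
#' deterministic given the seed.
#'
#' @param config An [encoder_config()].
#' @param seed Seed override (defaults to the config's).
#' @param vocab Optional `rxy_vocab` to attach (required for training and
#'   [encode()] on raw strings).
#' @return Model handle (environment of class `rxy_model` with `params`,
#'   `config`, `vocab`).
#' @export
init_model <- function(config, seed = config$seed, vocab = NULL) {
  stopifnot(inherits(config, "rxy_encoder_config"))
  if (!is.null(vocab) && vocab_size(vocab) != config$vocab_size) {
    rxy_abort("rxy_config_error", "vocab size disagrees with config vocab_size")
  }
  d <- config$hidden_size; f <- config$ff_size; V <- config$vocab_size
  params <- with_local_seed(seed, {
    w <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 0.02), nr, nc)
    p <- list(emb_tok = w(V, d), emb_pos = w(config$max_len, d))
    for (i in seq_len(config$n_layers)) {
      nm <- .layer_param_names(i)
      p[[nm[1L]]] <- w(d, d); p[[nm[2L]]] <- numeric(d)
      p[[nm[3L]]] <- w(d, d); p[[nm[4L]]] <- numeric(d)
      p[[nm[5L]]] <- w(d, d); p[[nm[6L]]] <- numeric(d)
      p[[nm[7L]]] <- w(d, d); p[[nm[8L]]] <- numeric(d)
      p[[nm[9L]]] <- rep(1, d); p[[nm[10L]]] <- numeric(d)
      p[[nm[11L]]] <- w(d, f); p[[nm[12L]]] <- numeric(f)
      p[[nm[13L]]] <- w(f, d); p[[nm[14L]]] <- numeric(d)
      p[[nm[15L]]] <- rep(1, d); p[[nm[16L]]] <- numeric(d)
    }
    p$mlm_W <- w(d, d); p$mlm_b <- numeric(d)
    p$mlm_ln_g <- rep(1, d); p$mlm_ln_b <- numeric(d)
    p$mlm_dec_b <- numeric(V)
    p
  })
  model <- new.env(parent = emptyenv())
  model$params <- params
  model$config <- config
  model$vocab <- vocab
  model$stage <- "initialized"
  class(model) <- "rxy_model"
  model
}

#' @export
print.rxy_model <- function(x, ...) {
  cat(sprintf("<rxy_model: %d layers, %d heads, d=%d, vocab=%d, %s; %d parameters>\n",
              x$config$n_layers, x$config$n_heads, x$config$hidden_size,
              x$config$vocab_size, x$stage, param_count(x)))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model An `rxy_model`.
#' @return Integer count.
#' @export
param_count <- function(model) {
  sum(vapply(model$params, length, 1L))
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

addb <- function(M, b) M + rep(b, each = nrow(M))

ln_fw <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + LN_EPS)
  xhat <- xc * inv
  list(Y = addb(sweep(xhat, 2L, g, `*`), b), xhat = xhat, inv = inv)
}

ln_bw <- function(dY, g, cache) {
  dxhat <- sweep(dY, 2L, g, `*`)
  list(dX = (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat)) * cache$inv,
       dg = colSums(dY * cache$xhat),
       db = colSums(dY))
}

softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

# Forward pass for one id sequence. Returns the final hidden states and, if
# `keep_cache`, everything the backward pass needs.
encoder_forward <- function(params, cfg, ids, train = FALSE, keep_cache = train) {
  L <- length(ids)
  if (L > cfg$max_len) {
    rxy_abort("rxy_length_error",
              sprintf("sequence length %d exceeds max_len %d (no silent truncation)",
                      L, cfg$max_len))
  }
  d <- cfg$hidden_size; H <- cfg$n_heads; dh <- d %/% H
  scale <- 1 / sqrt(dh)
  valid <- ids != 1L  # [PAD] id
  drop_p <- if (train) cfg$dropout else 0

  X <- params$emb_tok[ids, , drop = FALSE] + params$emb_pos[seq_len(L), , drop = FALSE]
  layers <- if (keep_cache) vector("list", cfg$n_layers) else NULL

  for (i in seq_len(cfg$n_layers)) {
    nm <- .layer_param_names(i)
    Wq <- params[[nm[1L]]]; bq <- params[[nm[2L]]]
    Wk <- params[[nm[3L]]]; bk <- params[[nm[4L]]]
    Wv <- params[[nm[5L]]]; bv <- params[[nm[6L]]]
    Wo <- params[[nm[7L]]]; bo <- params[[nm[8L]]]

    Q <- addb(X %*% Wq, bq); K <- addb(X %*% Wk, bk); Vm <- addb(X %*% Wv, bv)
    O <- matrix(0, L, d)
    A_list <- if (keep_cache) vector("list", H) else NULL
    for (h in seq_len(H)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) * scale
      if (!all(valid)) S[, !valid] <- -Inf
      A <- softmax_rows(S)
      O[, idx] <- A %*% Vm[, idx, drop = FALSE]
      if (keep_cache) A_list[[h]] <- A
    }
    attn <- addb(O %*% Wo, bo)
    dm1 <- NULL
    if (drop_p > 0) {
      dm1 <- matrix(stats::rbinom(L * d, 1L, 1 - drop_p), L, d) / (1 - drop_p)
      attn <- attn * dm1
    }
    R1 <- X + attn
    l1 <- ln_fw(R1, params[[nm[9L]]], params[[nm[10L]]])
    X1 <- l1$Y

    Hpre <- addb(X1 %*% params[[nm[11L]]], params[[nm[12L]]])
    G <- gelu(Hpre)
    Fout <- addb(G %*% params[[nm[13L]]], params[[nm[14L]]])
    dm2 <- NULL
    if (drop_p > 0) {
      dm2 <- matrix(stats::rbinom(L * d, 1L, 1 - drop_p), L, d) / (1 - drop_p)
      Fout <- Fout * dm2
    }
    R2 <- X1 + Fout
    l2 <- ln_fw(R2, params[[nm[15L]]], params[[nm[16L]]])

    if (keep_cache) {
      layers[[i]] <- list(X = X, Q = Q, K = K, V = Vm, A = A_list, O = O,
                          ln1 = l1, X1 = X1, Hpre = Hpre, G = G,
                          ln2 = l2, dm1 = dm1, dm2 = dm2)
    }
    X <- l2$Y
  }
  list(X = X, ids = ids, valid = valid, layers = layers)
}

# Backward pass; dX is the gradient at the final hidden states. Returns a
# gradient list keyed like params (embedding + layer entries only).
encoder_backward <- function(params, cfg, fw, dX) {
  d <- cfg$hidden_size; H <- cfg$n_heads; dh <- d %/% H
  scale <- 1 / sqrt(dh)
  L <- length(fw$ids)
  grads <- list()

  for (i in rev(seq_len(cfg$n_layers))) {
    nm <- .layer_param_names(i)
    cc <- fw$layers[[i]]

    b2 <- ln_bw(dX, params[[nm[15L]]], cc$ln2)
    grads[[nm[15L]]] <- b2$dg; grads[[nm[16L]]] <- b2$db
    dR2 <- b2$dX
    dFout <- if (!is.null(cc$dm2)) dR2 * cc$dm2 else dR2
    dX1 <- dR2

    dG <- dFout %*% t(params[[nm[13L]]])
    grads[[nm[13L]]] <- crossprod(cc$G, dFout)
    grads[[nm[14L]]] <- colSums(dFout)
    dHpre <- dG * gelu_grad(cc$Hpre)
    dX1 <- dX1 + dHpre %*% t(params[[nm[11L]]])
    grads[[nm[11L]]] <- crossprod(cc$X1, dHpre)
    grads[[nm[12L]]] <- colSums(dHpre)

    b1 <- ln_bw(dX1, params[[nm[9L]]], cc$ln1)
    grads[[nm[9L]]] <- b1$dg; grads[[nm[10L]]] <- b1$db
    dR1 <- b1$dX
    dAttn <- if (!is.null(cc$dm1)) dR1 * cc$dm1 else dR1
    dXl <- dR1  # residual path

    dO <- dAttn %*% t(params[[nm[7L]]])
    grads[[nm[7L]]] <- crossprod(cc$O, dAttn)
    grads[[nm[8L]]] <- colSums(dAttn)

    dQ <- matrix(0, L, d); dK <- matrix(0, L, d); dV <- matrix(0, L, d)
    for (h in seq_len(H)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cc$A[[h]]
      dOh <- dO[, idx, drop = FALSE]
      dA <- tcrossprod(dOh, cc$V[, idx, drop = FALSE])
      dV[, idx] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, idx] <- dS %*% cc$K[, idx, drop = FALSE] * scale
      dK[, idx] <- crossprod(dS, cc$Q[, idx, drop = FALSE]) * scale
    }
    grads[[nm[1L]]] <- crossprod(cc$X, dQ); grads[[nm[2L]]] <- colSums(dQ)
    grads[[nm[3L]]] <- crossprod(cc$X, dK); grads[[nm[4L]]] <- colSums(dK)
    grads[[nm[5L]]] <- crossprod(cc$X, dV); grads[[nm[6L]]] <- colSums(dV)
    dXl <- dXl + dQ %*% t(params[[nm[1L]]]) + dK %*% t(params[[nm[3L]]]) +
      dV %*% t(params[[nm[5L]]])
    dX <- dXl
  }

  dE <- matrix(0, cfg$vocab_size, d)
  for (j in seq_len(L)) dE[fw$ids[j], ] <- dE[fw$ids[j], ] + dX[j, ]
  grads$emb_tok <- dE
  dP <- matrix(0, cfg$max_len, d)
  dP[seq_len(L), ] <- dX
  grads$emb_pos <- dP
  grads
}

# MLM head forward at the masked positions. The decoder is tied to the token
# embedding matrix.
mlm_head_forward <- function(params, X, positions) {
  Hrow <- X[positions, , drop = FALSE]
  Z <- addb(Hrow %*% params$mlm_W, params$mlm_b)
  G <- gelu(Z)
  ln <- ln_fw(G, params$mlm_ln_g, params$mlm_ln_b)
  logits <- addb(tcrossprod(ln$Y, params$emb_tok), params$mlm_dec_b)
  list(logits = logits, Hrow = Hrow, Z = Z, G = G, ln = ln)
}

mlm_head_backward <- function(params, head, dlogits, positions, L) {
  grads <- list()
  grads$mlm_dec_b <- colSums(dlogits)
  dHn <- dlogits %*% params$emb_tok
  dE_dec <- crossprod(dlogits, head$ln$Y)
  b <- ln_bw(dHn, params$mlm_ln_g, head$ln)
  grads$mlm_ln_g <- b$dg; grads$mlm_ln_b <- b$db
  dZ <- b$dX * gelu_grad(head$Z)
  grads$mlm_W <- crossprod(head$Hrow, dZ)
  grads$mlm_b <- colSums(dZ)
  dHrow <- dZ %*% t(params$mlm_W)
  dX <- matrix(0, L, ncol(dHrow))
  dX[positions, ] <- dHrow
  list(grads = grads, dX = dX, dE_dec = dE_dec)
}

.as_id_list <- function(model, x) {
  if (is.character(x)) {
    if (is.null(model$vocab)) {
      rxy_abort("rxy_config_error", "model has no attached vocabulary; pass token sequences")
    }
    lapply(x, function(s) token_sequence(s, model$vocab)$ids)
  } else if (inherits(x, "rxy_token_seq")) {
    list(x$ids)
  } else if (is.list(x)) {
    lapply(x, function(s) if (inherits(s, "rxy_token_seq")) s$ids else as.integer(s))
  } else {
    list(as.integer(x))
  }
}

#' Encode reactions into fixed-length embeddings
#'
#' Runs the encoder in evaluation mode (deterministic) and returns the final
#' hidden vector at the `[CLS]` position of each sequence.
#'
#' @param model An `rxy_model`.
#' @param x Character vector of reaction SMILES, an `rxy_token_seq`, or a
#'   list of token sequences / id vectors.
#' @return Numeric matrix, one row per input, `hidden_size` columns.
#' @export
encode <- function(model, x) {
  ids_list <- .as_id_list(model, x)
  out <- matrix(0, length(ids_list), model$config$hidden_size)
  for (i in seq_along(ids_list)) {
    fw <- encoder_forward(model$params, model$config, ids_list[[i]],
                          train = FALSE, keep_cache = FALSE)
    out[i, ] <- fw$X[1L, ]
  }
  out
}

#' Vocabulary logits at the masked positions of a batch
#'
#' @param model An `rxy_model`.
#' @param masked An `rxy_masked` batch from [mask_tokens()].
#' @return Matrix with one row per masked position, `vocab_size` columns.
#' @export
mlm_logits <- function(model, masked) {
  stopifnot(inherits(masked, "rxy_masked"))
  if (length(masked$positions) == 0L) {
    return(matrix(0, 0L, model$config$vocab_size))
  }
  fw <- encoder_forward(model$params, model$config, masked$ids,
                        train = FALSE, keep_cache = FALSE)
  mlm_head_forward(model$params, fw$X, masked$positions)$logits
}

#' Save / load model checkpoints
#'
#' The checkpoint stores the parameters, encoder config, vocabulary (plus
#' its content hash) and the training stage tag; loading reproduces encoder
#' outputs bitwise.
#'
#' @param model An `rxy_model`.
#' @param path File path.
#' @return `path` invisibly (save); an `rxy_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "rxy_ckpt_v1", params = model$params,
               config = model$config, vocab = model$vocab,
               vocab_hash = if (!is.null(model$vocab)) vocab_hash(model$vocab) else NA_character_,
               stage = model$stage),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) e)
  if (inherits(obj, "error") || !is.list(obj) ||
      !identical(obj$format, "rxy_ckpt_v1")) {
    rxy_abort("rxy_checkpoint_error",
              sprintf("'%s' is not a readable rxnyield checkpoint", path))
  }
  if (!is.null(obj$vocab) && !identical(vocab_hash(obj$vocab), obj$vocab_hash)) {
    rxy_abort("rxy_checkpoint_error", "vocabulary hash mismatch in checkpoint")
  }
  model <- new.env(parent = emptyenv())
  model$params <- obj$params
  model$config <- obj$config
  model$vocab <- obj$vocab
  model$stage <- obj$stage
  class(model) <- "rxy_model"
  model
}

#' Copy a model handle
#'
#' Returns an independent handle (used for architecture-matched twins,
#' meta-learning clones, and best-checkpoint selection); the original is
#' never affected by training the copy.
#'
#' @param model An `rxy_model`.
#' @return A new `rxy_model`.
#' @export
clone_model <- function(model) {
  m <- new.env(parent = emptyenv())
  m$params <- model$params
  m$config <- model$config
  m$vocab <- model$vocab
  m$stage <- model$stage
  class(m) <- "rxy_model"
  m
}
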