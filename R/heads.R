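# Fine-tuning heads: small feedforward networks on top of the [CLS]
# reaction embedding. Regression squashes through a sigmoid so predictions
# live on the fractional yield scale [0,1]; the 4-class head emits a
# softmax over (extremely_low, low, medium, high).

#' Head configuration
#'
#' @param kind `"regression"` (fractional yield in `[0,1]`) or
#'   `"multiclass4"` (probabilities over the four yield classes, ordered
#'   extremely_low, low, medium, high).
#' @param hidden Width of the hidden layer.
#' @param dropout Dropout on the hidden layer during training.
#' @return List of class `rxy_head_config`.
#' @export
head_config <- function(kind = c("regression", "multiclass4"), hidden = 64L,
                        dropout = 0) {
  out <- list(kind = match.arg(kind), hidden = as.integer(hidden),
              dropout = as.numeric(dropout))
  if (out$hidden < 1L || out$dropout < 0 || out$dropout >= 1) {
    rxy_abort("rxy_config_error", "invalid head configuration")
  }
  class(out) <- "rxy_head_config"
  out
}

init_head <- function(cfg, d, seed = 1L) {
  k_out <- if (cfg$kind == "regression") 1L else 4L
  with_local_seed(seed, {
    w <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 0.05), nr, nc)
    list(W1 = w(d, cfg$hidden), b1 = numeric(cfg$hidden),
         W2 = w(cfg$hidden, k_out), b2 = numeric(k_out))
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

head_forward <- function(head_params, cfg, emb, train = FALSE) {
  Z1 <- addb(emb %*% head_params$W1, head_params$b1)
  Hh <- pmax(Z1, 0)
  dm <- NULL
  if (train && cfg$dropout > 0) {
    dm <- matrix(stats::rbinom(length(Hh), 1L, 1 - cfg$dropout),
                 nrow(Hh), ncol(Hh)) / (1 - cfg$dropout)
    Hh <- Hh * dm
  }
  Z2 <- addb(Hh %*% head_params$W2, head_params$b2)
  out <- if (cfg$kind == "regression") {
    sigmoid(Z2)
  } else {
    exp(log_softmax_rows(Z2))
  }
  list(out = out, Z1 = Z1, H = Hh, Z2 = Z2, emb = emb, dm = dm)
}

# dZ2 is the gradient at the pre-activation output; returns head gradients
# and the gradient flowing into the embeddings.
head_backward <- function(head_params, cfg, cache, dZ2) {
  gW2 <- crossprod(cache$H, dZ2)
  gb2 <- colSums(dZ2)
  dH <- dZ2 %*% t(head_params$W2)
  if (!is.null(cache$dm)) dH <- dH * cache$dm
  dZ1 <- dH * (cache$Z1 > 0)
  gW1 <- crossprod(cache$emb, dZ1)
  gb1 <- colSums(dZ1)
  demb <- dZ1 %*% t(head_params$W1)
  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2), demb = demb)
}

#' Predict yields or yield-class probabilities from embeddings
#'
#' @param model An `rxy_model` (used for dimension checking only).
#' @param embeddings Matrix of reaction embeddings (rows = reactions).
#' @param head A trained head (list with `params` and `config`) as stored in
#'   an `rxy_task_model`, or an `rxy_head_config` to use a freshly
#'   initialized head.
#' @return Regression: numeric vector in `[0,1]`. Multiclass: matrix of four
#'   class probabilities per row (columns extremely_low, low, medium, high).
#' @export
predict_head <- function(model, embeddings, head) {
  if (inherits(head, "rxy_head_config")) {
    head <- list(params = init_head(head, model$config$hidden_size), config = head)
  }
  if (ncol(embeddings) != nrow(head$params$W1)) {
    rxy_abort("rxy_shape_error",
              sprintf("embedding dimension %d does not match head input %d",
                      ncol(embeddings), nrow(head$params$W1)))
  }
  out <- head_forward(head$params, head$config, embeddings, train = FALSE)$out
  if (head$config$kind == "regression") {
    as.numeric(out)
  } else {
    colnames(out) <- YIELD_BIN_LEVELS
    out
  }
}
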