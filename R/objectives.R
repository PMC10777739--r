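# Loss functions: cosine similarity, the condition-contrastive loss, MLM
# cross-entropy, and the combined stage-2 objective.
#
# The contrastive loss over a batch of N reactions is
#   CL = alpha * sum_n sum_{i in I_n} cos(V_nc, V_ni)
#          +     sum_n sum_{p in P_n} (1 - cos(V_nc, V_np)) / 2
# with I_n the condition-replaced negatives and P_n the permuted-SMILES
# positives of reaction n. alpha balances the two terms; of the candidate
# values {0.02, 0.05, 1}, 0.02 converges most stably and is the default.
# Written as a sum over the batch ("sum_as_written"); a mean reduction
# (divide by N) is available as a config switch.

#' Contrastive loss configuration
#'
#' @param alpha Balance coefficient for the negative term (> 0; default
#'   0.02, the most stable of the candidate values 0.02 / 0.05 / 1).
#' @param reduction `"sum_as_written"` (double sum over the batch) or
#'   `"mean"` (divided by the number of reactions).
#' @return List of class `rxy_loss_config`.
#' @export
loss_config <- function(alpha = 0.02, reduction = c("sum_as_written", "mean")) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    rxy_abort("rxy_config_error", "alpha must be a single positive number")
  }
  out <- list(alpha = alpha, reduction = match.arg(reduction))
  class(out) <- "rxy_loss_config"
  out
}

#' Cosine similarity of two embeddings
#'
#' `(Va . Vb) / (||Va|| ||Vb||)` with Euclidean norms.
#'
#' @param va,vb Non-zero numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(va, vb) {
  stopifnot(length(va) == length(vb))
  na <- sqrt(sum(va * va)); nb <- sqrt(sum(vb * vb))
  if (na == 0 || nb == 0) {
    rxy_abort("rxy_zero_vector_error", "cosine similarity of a zero vector is undefined")
  }
  sum(va * vb) / (na * nb)
}

# d cos(a, b) / d a  (used by the training loop)
.cos_grad_a <- function(va, vb) {
  na <- sqrt(sum(va * va)); nb <- sqrt(sum(vb * vb))
  cs <- sum(va * vb) / (na * nb)
  vb / (na * nb) - cs * va / (na * na)
}

.check_triplet_embeddings <- function(batch) {
  for (n in seq_along(batch)) {
    tr <- batch[[n]]
    if (length(tr$positives) == 0L || length(tr$negatives) == 0L) {
      rxy_abort("rxy_degenerate_triplet_error",
                sprintf("reaction %d lacks a positive or negative embedding", n))
    }
  }
}

#' Condition-contrastive loss over a batch of embeddings
#'
#' @param batch List over reactions; each element is
#'   `list(anchor = vector, positives = list of vectors, negatives = list of
#'   vectors)`.
#' @param config A [loss_config()].
#' @return Scalar loss (may be negative: collinear anchor/negative pairs
#'   contribute `+alpha` each, anti-collinear pairs `-alpha`).
#' @export
contrastive_loss <- function(batch, config = loss_config()) {
  stopifnot(inherits(config, "rxy_loss_config"))
  .check_triplet_embeddings(batch)
  total <- 0
  for (tr in batch) {
    for (vi in tr$negatives) total <- total + config$alpha * cosine_similarity(tr$anchor, vi)
    for (vp in tr$positives) total <- total + 0.5 * (1 - cosine_similarity(tr$anchor, vp))
  }
  if (config$reduction == "mean") total <- total / length(batch)
  total
}

# Gradients of contrastive_loss with respect to every embedding in the
# batch; mirrors the structure of `batch`.
contrastive_loss_grads <- function(batch, config = loss_config()) {
  .check_triplet_embeddings(batch)
  scale <- if (config$reduction == "mean") 1 / length(batch) else 1
  lapply(batch, function(tr) {
    d_anchor <- numeric(length(tr$anchor))
    d_neg <- lapply(tr$negatives, function(vi) {
      d_anchor <<- d_anchor + config$alpha * .cos_grad_a(tr$anchor, vi) * scale
      config$alpha * .cos_grad_a(vi, tr$anchor) * scale
    })
    d_pos <- lapply(tr$positives, function(vp) {
      d_anchor <<- d_anchor - 0.5 * .cos_grad_a(tr$anchor, vp) * scale
      -0.5 * .cos_grad_a(vp, tr$anchor) * scale
    })
    list(anchor = d_anchor, positives = d_pos, negatives = d_neg)
  })
}

# Row-wise log-softmax, numerically stable.
log_softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  S - m - log(rowSums(exp(S - m)))
}

#' Masked-language-model cross-entropy
#'
#' Mean cross-entropy of the logits against the true token ids at the masked
#' positions.
#'
#' @param logits Matrix, one row per masked position.
#' @param masked The `rxy_masked` batch the logits were computed for.
#' @return Scalar loss (>= 0).
#' @export
mlm_loss <- function(logits, masked) {
  stopifnot(inherits(masked, "rxy_masked"))
  n <- length(masked$positions)
  if (n == 0L) {
    rxy_abort("rxy_no_mask_error", "no masked positions; MLM loss undefined")
  }
  stopifnot(nrow(logits) == n)
  ls <- log_softmax_rows(logits)
  -mean(ls[cbind(seq_len(n), masked$labels)])
}

# d(mean CE)/d logits: (softmax - onehot) / n
mlm_loss_grad <- function(logits, labels) {
  n <- nrow(logits)
  P <- exp(log_softmax_rows(logits))
  P[cbind(seq_len(n), labels)] <- P[cbind(seq_len(n), labels)] - 1
  P / n
}

#' Combined stage-2 loss
#'
#' The second pretraining stage optimizes the exact sum of the MLM
#' cross-entropy and the contrastive loss.
#'
#' @param mlm,cl Component losses on the same batch.
#' @return List with `total`, `mlm`, `cl` (total = mlm + cl).
#' @export
combined_loss <- function(mlm, cl) {
  list(total = mlm + cl, mlm = mlm, cl = cl)
}
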