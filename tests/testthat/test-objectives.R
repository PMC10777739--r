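# Loss functions: cosine, contrastive, MLM cross-entropy, combined.

test_that("cosine similarity matches its definition", {
  v <- c(0.3, -1.2, 4)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2), c(2, 1)), 0.8)
  expect_equal(cosine_similarity(3 * v, 0.1 * v), 1)  # scale invariance
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), class = "rxy_zero_vector_error")
})

test_that("contrastive loss reproduces hand-derived fixed-vector values", {
  cfg <- loss_config(alpha = 0.02)
  mk <- function(anchor, neg, pos) list(list(anchor = anchor,
                                             negatives = list(neg),
                                             positives = list(pos)))
  # separated: negative orthogonal (cos 0), positive collinear (cos 1)
  expect_equal(contrastive_loss(mk(c(1, 0), c(0, 1), c(1, 0)), cfg), 0)
  # confused: negative collinear, positive orthogonal
  expect_equal(contrastive_loss(mk(c(1, 0), c(1, 0), c(0, 1)), cfg), 0.52)
  # ideal: negative anti-collinear -> the loss goes negative
  expect_equal(contrastive_loss(mk(c(1, 0), c(-1, 0), c(1, 0)), cfg), -0.02)
})

test_that("contrastive loss honours alpha, reduction, bounds, and scale invariance", {
  set.seed(3)
  batch <- lapply(1:4, function(i)
    list(anchor = rnorm(6),
         negatives = lapply(1:3, function(j) rnorm(6)),
         positives = lapply(1:2, function(j) rnorm(6))))
  cl_sum <- contrastive_loss(batch, loss_config(alpha = 0.05))
  expect_equal(contrastive_loss(batch, loss_config(alpha = 0.05, reduction = "mean")),
               cl_sum / 4)
  n_neg <- 12; n_pos <- 8
  expect_gte(cl_sum, -0.05 * n_neg)
  expect_lte(cl_sum, 0.05 * n_neg + n_pos)
  scaled <- lapply(batch, function(tr)
    list(anchor = 3 * tr$anchor,
         negatives = lapply(tr$negatives, function(v) 3 * v),
         positives = lapply(tr$positives, function(v) 3 * v)))
  expect_equal(contrastive_loss(scaled, loss_config(alpha = 0.05)), cl_sum)
  expect_error(contrastive_loss(list(list(anchor = 1:3, negatives = list(),
                                          positives = list(1:3)))),
               class = "rxy_degenerate_triplet_error")
})

test_that("gradient descent on free embeddings reaches the analytic minimum", {
  # minimum over unit vectors: positives collinear, negatives anti-collinear,
  # so CL -> -alpha * total negatives
  cfg <- loss_config(alpha = 0.02)
  set.seed(11)
  batch <- lapply(1:3, function(i)
    list(anchor = rnorm(4),
         negatives = lapply(1:2, function(j) rnorm(4)),
         positives = list(rnorm(4))))
  for (step in 1:1500) {
    g <- rxnyield:::contrastive_loss_grads(batch, cfg)
    for (i in seq_along(batch)) {
      batch[[i]]$anchor <- batch[[i]]$anchor - 0.5 * g[[i]]$anchor
      for (j in seq_along(batch[[i]]$negatives)) {
        batch[[i]]$negatives[[j]] <- batch[[i]]$negatives[[j]] - 0.5 * g[[i]]$negatives[[j]]
      }
      for (j in seq_along(batch[[i]]$positives)) {
        batch[[i]]$positives[[j]] <- batch[[i]]$positives[[j]] - 0.5 * g[[i]]$positives[[j]]
      }
    }
  }
  expect_lt(abs(contrastive_loss(batch, cfg) - (-0.02 * 6)), 1e-3)
})

test_that("contrastive gradients match finite differences", {
  cfg <- loss_config(alpha = 0.05)
  set.seed(5)
  batch <- list(list(anchor = rnorm(5), negatives = list(rnorm(5), rnorm(5)),
                     positives = list(rnorm(5))))
  g <- rxnyield:::contrastive_loss_grads(batch, cfg)[[1]]
  eps <- 1e-6
  for (k in 1:5) {
    b2 <- batch; b2[[1]]$anchor[k] <- b2[[1]]$anchor[k] + eps
    b3 <- batch; b3[[1]]$anchor[k] <- b3[[1]]$anchor[k] - eps
    num <- (contrastive_loss(b2, cfg) - contrastive_loss(b3, cfg)) / (2 * eps)
    expect_equal(g$anchor[k], num, tolerance = 1e-5)
  }
})

test_that("MLM loss equals ln(V) under uniform scores and 0 when certain", {
  v <- fx_vocab()
  seq <- token_sequence("CCO>O>CCO", v)
  m <- mask_tokens(seq, v, 0.3, seed = 2)
  n <- length(m$positions)
  V <- vocab_size(v)
  uni <- matrix(0, n, V)
  expect_equal(mlm_loss(uni, m), log(V), tolerance = 1e-12)
  onehot <- matrix(-1e4, n, V)
  onehot[cbind(seq_len(n), m$labels)] <- 1e4
  expect_equal(mlm_loss(onehot, m), 0, tolerance = 1e-9)
  # invariant to reordering the masked positions
  perm <- sample(n)
  m2 <- m; m2$positions <- m$positions[perm]; m2$labels <- m$labels[perm]
  set.seed(4); L <- matrix(rnorm(n * V), n, V)
  expect_equal(mlm_loss(L[perm, , drop = FALSE], m2), mlm_loss(L, m))
  m0 <- mask_tokens(seq, v, 0, seed = 1)
  expect_error(mlm_loss(matrix(0, 0, V), m0), class = "rxy_no_mask_error")
})

test_that("combined loss is the exact sum of its components", {
  expect_equal(combined_loss(0.7, 0.3)$total, 1)
  expect_equal(combined_loss(2.5, 0)$total, 2.5)
  cl <- combined_loss(1.2, -0.4)
  expect_identical(cl$total, cl$mlm + cl$cl)
  # additivity of gradients on a 2-parameter toy model, by finite differences
  f_mlm <- function(w) (w[1] - 2)^2
  f_cl <- function(w) sin(w[2])
  w <- c(0.5, 0.8); eps <- 1e-6
  for (k in 1:2) {
    e <- numeric(2); e[k] <- eps
    g_sum <- (combined_loss(f_mlm(w + e), f_cl(w + e))$total -
                combined_loss(f_mlm(w - e), f_cl(w - e))$total) / (2 * eps)
    g_parts <- (f_mlm(w + e) - f_mlm(w - e)) / (2 * eps) +
      (f_cl(w + e) - f_cl(w - e)) / (2 * eps)
    expect_equal(g_sum, g_parts, tolerance = 1e-8)
  }
})
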