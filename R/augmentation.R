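# Pretraining inputs: randomized-SMILES positives, condition-replaced
# negatives, and masked-token batches.
#
# Positives re-serialize every molecule of the anchor with a randomized atom
# ordering, so they canonicalize back to the anchor. Negatives keep the reactant/product segments
# byte-identical and replace part of the condition multiset with same-role
# catalog entries. All randomness is seeded.

# How many randomized candidate forms to request per fragment before falling
# back to the canonical form (single-atom molecules have only one form).
POSITIVE_RETRIES <- 10L

# Assemble one permuted reaction string from per-fragment randomized forms.
# `forms` maps "<fragment>\r<seed>" to a vector of candidate serializations.
.assemble_positive <- function(anchor, forms, seed) {
  seg <- split_reaction(anchor)
  pick <- function(frag, s) {
    cand <- forms[[paste0(frag, "\r", s)]]
    alt <- cand[cand != frag]
    if (length(alt)) alt[[1L]] else frag
  }
  out <- lapply(names(seg), function(nm) {
    frs <- seg[[nm]]
    if (length(frs) == 0L) return(character(0))
    vapply(seq_along(frs), function(i) {
      pick(frs[i], derive_seed(seed, paste0(anchor, "_", nm, "_", i)))
    }, "")
  })
  names(out) <- names(seg)
  join_reaction(out)
}

# Collect the randomized-form requests one anchor needs.
.positive_requests <- function(anchor, seed) {
  seg <- split_reaction(anchor)
  reqs <- list()
  for (nm in names(seg)) {
    frs <- seg[[nm]]
    for (i in seq_along(frs)) {
      reqs[[length(reqs) + 1L]] <-
        c(frs[i], derive_seed(seed, paste0(anchor, "_", nm, "_", i)))
    }
  }
  reqs
}

# One bridge call serving many (fragment, seed) requests.
.fetch_random_forms <- function(requests) {
  if (length(requests) == 0L) return(list())
  frag <- vapply(requests, `[`, "", 1L)
  seeds <- as.integer(vapply(requests, `[`, "", 2L))
  key <- paste0(frag, "\r", seeds)
  dup <- duplicated(key)
  res <- random_smiles(frag[!dup], n = POSITIVE_RETRIES, seed = seeds[!dup])
  stats::setNames(res, key[!dup])
}

#' Generate a positive (permuted) variant of a canonical reaction SMILES
#'
#' Every molecule is rewritten with a randomized atom ordering; the result
#' canonicalizes back to the anchor. Anchors whose molecules admit only one
#' serialization (e.g. single atoms) are returned unchanged.
#'
#' @param anchor Canonical reaction SMILES.
#' @param seed Integer seed.
#' @return A reaction SMILES string.
#' @export
make_positive <- function(anchor, seed = 1L) {
  forms <- .fetch_random_forms(.positive_requests(anchor, seed))
  .assemble_positive(anchor, forms, seed)
}

#' Generate negative (condition-replaced) variants of a reaction SMILES
#'
#' Each negative replaces between 1 and all condition fragments (count drawn
#' uniformly) with same-role catalog entries not already present in the
#' anchor; reactant and product segments are untouched. Falls back to
#' any-role replacement (with a warning) when a role's catalog is exhausted.
#'
#' @param anchor Canonical reaction SMILES with a non-empty condition
#'   segment.
#' @param catalog Role-keyed condition lists (canonical SMILES).
#' @param k Number of negatives.
#' @param seed Integer seed.
#' @return Character vector of `k` reaction SMILES.
#' @export
make_negatives <- function(anchor, catalog, k = 2L, seed = 1L) {
  seg <- split_reaction(anchor)
  conds <- seg$conditions
  if (length(conds) == 0L) {
    rxy_abort("rxy_no_conditions_error",
              sprintf("anchor '%s' has no condition fragments to replace", anchor))
  }
  pool_all <- setdiff(unlist(catalog, use.names = FALSE), conds)
  if (length(pool_all) == 0L) {
    rxy_abort("rxy_catalog_error", "catalog has no conditions outside the anchor's own")
  }
  with_local_seed(derive_seed(seed, paste0("neg_", anchor)), {
    vapply(seq_len(k), function(j) {
      m <- sample.int(length(conds), 1L)
      repl_pos <- sample.int(length(conds), m)
      new_conds <- conds
      for (p in repl_pos) {
        role <- condition_role(conds[p], catalog)
        pool <- if (!is.na(role)) setdiff(catalog[[role]], conds) else character(0)
        if (length(pool) == 0L) {
          if (is.na(role)) {
            rxy_warn(sprintf("condition '%s' not in catalog; any-role replacement used",
                             conds[p]))
          } else {
            rxy_warn(sprintf("catalog exhausted for role '%s'; any-role replacement used",
                             role))
          }
          pool <- pool_all
        }
        new_conds[p] <- if (length(pool) == 1L) pool else sample(pool, 1L)
      }
      seg$conditions <- sort(new_conds, method = "radix")
      join_reaction(seg)
    }, "")
  })
}

#' Mask tokens of a sequence for masked-language-model training
#'
#' Selects exactly `round(rate * n_maskable)` non-special positions. Of the
#' selected positions, 80% become `[MASK]`, 10% a random vocabulary token,
#' and 10% stay unchanged; the labels are the original ids at the selected
#' positions.
#'
#' @param seq An `rxy_token_seq` (see [token_sequence()]).
#' @param vocab The `rxy_vocab` the sequence was encoded with.
#' @param rate Masking rate in `[0,1]` (default 0.15).
#' @param seed Integer seed.
#' @return List of class `rxy_masked` with `ids` (corrupted), `labels`
#'   (original ids at masked positions), `positions`, and the original
#'   `seq`.
#' @export
mask_tokens <- function(seq, vocab, rate = 0.15, seed = 1L) {
  stopifnot(inherits(seq, "rxy_token_seq"), rate >= 0, rate <= 1)
  maskable <- setdiff(seq_along(seq$ids), seq$specials)
  n_sel <- round(rate * length(maskable))
  out <- list(ids = seq$ids, labels = integer(0), positions = integer(0),
              seq = seq)
  class(out) <- "rxy_masked"
  if (n_sel == 0L) return(out)
  with_local_seed(derive_seed(seed, "mask"), {
    pos <- sort(sample(maskable, n_sel))
    out$positions <- pos
    out$labels <- seq$ids[pos]
    action <- sample(c("mask", "random", "keep"), n_sel, replace = TRUE,
                     prob = c(0.8, 0.1, 0.1))
    non_reserved <- seq(length(RESERVED_TOKENS) + 1L, vocab_size(vocab))
    for (i in seq_len(n_sel)) {
      if (action[i] == "mask") {
        out$ids[pos[i]] <- vocab$mask
      } else if (action[i] == "random") {
        out$ids[pos[i]] <- if (length(non_reserved) == 1L) non_reserved else
          sample(non_reserved, 1L)
      }
    }
  })
  out
}

#' Build a batch of contrastive triplets
#'
#' One triplet (anchor, `n_pos` positives, `n_neg` negatives) per record.
#' Records without condition fragments are skipped with a warning that
#' reports the count; randomized-SMILES generation for the whole batch is
#' served by a single helper invocation.
#'
#' @param records Reaction record data.frame (canonical SMILES).
#' @param catalog Role-keyed condition lists.
#' @param n_pos,n_neg Positives / negatives per anchor.
#' @param seed Integer seed.
#' @return List of triplets, each `list(anchor, positives, negatives)`.
#' @export
build_contrastive_batch <- function(records, catalog, n_pos = 1L, n_neg = 2L,
                                    seed = 1L) {
  anchors <- records$reaction_smiles
  has_cond <- vapply(anchors,
                     function(a) length(split_reaction(a)$conditions) > 0L,
                     logical(1), USE.NAMES = FALSE)
  if (!any(has_cond)) {
    rxy_abort("rxy_empty_batch_error",
              "no record has condition fragments; cannot build a contrastive batch")
  }
  if (any(!has_cond)) {
    rxy_warn(sprintf("%d record(s) without conditions skipped", sum(!has_cond)))
  }
  keep <- which(has_cond)

  # one bridge call for every positive of every record
  reqs <- list()
  for (i in keep) {
    for (p in seq_len(n_pos)) {
      reqs <- c(reqs, .positive_requests(anchors[i], derive_seed(seed, paste0(i, "_", p))))
    }
  }
  forms <- .fetch_random_forms(reqs)

  lapply(keep, function(i) {
    positives <- vapply(seq_len(n_pos), function(p) {
      .assemble_positive(anchors[i], forms, derive_seed(seed, paste0(i, "_", p)))
    }, "")
    negatives <- make_negatives(anchors[i], catalog, k = n_neg,
                                seed = derive_seed(seed, paste0("neg", i)))
    list(anchor = anchors[i], positives = positives, negatives = negatives)
  })
}
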