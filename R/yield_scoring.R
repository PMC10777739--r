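# Yield-incorporated scoring of single-step retrosynthesis expansions.
#
# A template-based single-step model proposes expansion candidates, each
# with a template prior in [0,1]; a condition source attaches predicted
# conditions to the step; the 4-class yield model scores the conditioned
# reaction; and the candidate's prior is re-weighted by its expected yield
# so that route search expands likely high-yield steps first. The route
# search itself is out of scope -- this module scores and ranks candidates
# and ships a small best-first search used to study the ranking's effect on
# mock trees with known step yields.

#' Expected percent yield of a 4-class prediction
#'
#' Probability-weighted mean of the bin midpoints (15, 40, 65, 90 percent
#' for extremely_low, low, medium, high).
#'
#' @param class_probs Numeric vector of 4 probabilities (ordered
#'   extremely_low, low, medium, high) or a matrix with one such row per
#'   reaction.
#' @return Expected yield(s) in percent, within `[15, 90]`.
#' @export
expected_yield <- function(class_probs) {
  if (is.matrix(class_probs)) {
    return(apply(class_probs, 1L, expected_yield))
  }
  if (length(class_probs) != 4L || any(class_probs < 0) ||
      abs(sum(class_probs) - 1) > 1e-6) {
    rxy_abort("rxy_normalization_error",
              "class_probs must be 4 non-negative probabilities summing to 1")
  }
  sum(class_probs * unname(BIN_CENTERS))
}

#' Combine a template prior with an expected yield
#'
#' Default rule is multiplicative: `prior * expected_yield / 100`, which is
#' monotone in both arguments, never exceeds the template prior, and leaves
#' the prior unchanged at 100% expected yield. A weighted-geometric
#' alternative `prior^(1-w) * (yield/100)^w` is available.
#'
#' @param template_prior Prior score(s) in `[0,1]`.
#' @param expected_yield_percent Expected yield(s) in percent.
#' @param rule `"product"` or `"geometric"`.
#' @param weight Yield weight for the geometric rule (in `[0,1]`).
#' @return Combined prior score(s).
#' @export
yield_incorporated_prior <- function(template_prior, expected_yield_percent,
                                     rule = c("product", "geometric"),
                                     weight = 0.5) {
  rule <- match.arg(rule)
  frac <- expected_yield_percent / 100
  if (rule == "product") {
    template_prior * frac
  } else {
    template_prior^(1 - weight) * frac^weight
  }
}

#' Rank expansion candidates by yield-incorporated prior
#'
#' Each candidate reaction gets conditions from `condition_source`, a
#' 4-class yield prediction from the model, and a combined prior; the
#' result is sorted by combined prior (descending), ties broken by template
#' prior then input order. Candidates whose scoring fails are kept, ranked
#' last, and annotated with the failure reason.
#'
#' @param candidates data.frame with columns `reaction_smiles` and
#'   `template_prior` (rows are single-step candidates; the condition
#'   segment may be empty if `condition_source` supplies one).
#' @param task_model An `rxy_task_model` with a multiclass4 head.
#' @param condition_source Optional `function(reaction_smiles) -> reaction
#'   smiles with conditions`; identity if NULL.
#' @param rule,weight Passed to [yield_incorporated_prior()].
#' @return The candidates with `expected_yield`, `combined_prior`, `rank`,
#'   `status` columns, sorted by rank.
#' @export
rank_expansions <- function(candidates, task_model, condition_source = NULL,
                            rule = "product", weight = 0.5) {
  stopifnot(is.data.frame(candidates),
            all(c("reaction_smiles", "template_prior") %in% names(candidates)))
  n <- nrow(candidates)
  ey <- rep(NA_real_, n)
  status <- rep("ok", n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      smi <- candidates$reaction_smiles[i]
      if (!is.null(condition_source)) smi <- condition_source(smi)
      probs <- predict_yields(task_model,
                              data.frame(record_id = sprintf("C%05d", i),
                                         reaction_smiles = smi,
                                         stringsAsFactors = FALSE))
      if (nrow(probs) == 0L) stop("tokenization failed")
      expected_yield(as.numeric(as.matrix(probs[1L, YIELD_BIN_LEVELS])))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- conditionMessage(res)
    } else {
      ey[i] <- res
    }
  }
  combined <- ifelse(status == "ok",
                     yield_incorporated_prior(candidates$template_prior, ey,
                                              rule = rule, weight = weight),
                     -Inf)
  ord <- order(-combined, -candidates$template_prior, seq_len(n))
  out <- candidates[ord, , drop = FALSE]
  out$expected_yield <- ey[ord]
  out$combined_prior <- ifelse(is.finite(combined[ord]), combined[ord], NA_real_)
  out$status <- status[ord]
  out$rank <- seq_len(n)
  rownames(out) <- NULL
  out
}

#' Generate a mock retrosynthesis search tree with known step yields
#'
#' Every internal node offers `branching` candidate expansions, each with a
#' template prior (independent of yield) and a true percent yield. A route
#' is a root-to-leaf path; its quality is the product of its step yield
#' fractions. Used to study how yield-aware ranking steers best-first
#' search.
#'
#' @param depth Route length.
#' @param branching Candidates per node.
#' @param seed Integer seed.
#' @return List of class `rxy_route_tree` with `depth`, `branching`,
#'   `edges` (data.frame: node ids, template_prior, yield_percent).
#' @export
random_route_tree <- function(depth = 3L, branching = 3L, seed = 1L) {
  n_nodes <- sum(branching^(0:depth))
  with_local_seed(derive_seed(seed, "route_tree"), {
    parents <- integer(0); children <- integer(0)
    nxt <- 2L
    frontier <- 1L
    for (d in seq_len(depth)) {
      new_frontier <- integer(0)
      for (p in frontier) {
        kids <- nxt:(nxt + branching - 1L)
        nxt <- nxt + branching
        parents <- c(parents, rep(p, branching))
        children <- c(children, kids)
        new_frontier <- c(new_frontier, kids)
      }
      frontier <- new_frontier
    }
    edges <- data.frame(parent = parents, child = children,
                        template_prior = stats::runif(length(parents), 0.05, 1),
                        yield_percent = stats::runif(length(parents), 5, 95))
    structure(list(depth = depth, branching = branching, edges = edges,
                   n_nodes = n_nodes),
              class = "rxy_route_tree")
  })
}

# True best route of a tree: maximum product of step yield fractions.
best_route_yield <- function(tree) {
  e <- tree$edges
  score <- c(1, rep(NA_real_, max(e$child) - 1L))
  for (i in seq_len(nrow(e))) {
    score[e$child[i]] <- score[e$parent[i]] * e$yield_percent[i] / 100
  }
  leaves <- setdiff(e$child, e$parent)
  leaves[which.max(score[leaves])]
}

#' Best-first route search on a mock tree
#'
#' Expands nodes in order of a cumulative edge score: the product of
#' template priors (`use_yield = FALSE`) or of yield-incorporated priors
#' computed by [yield_incorporated_prior()] from the predicted expected
#' yield (`use_yield = TRUE`). The yield predictor is emulated by an
#' oracle-with-noise: predicted expected yield = true yield + N(0, sd).
#' Returns the number of node expansions needed before the true
#' highest-yield route is fully expanded.
#'
#' @param tree An `rxy_route_tree`.
#' @param use_yield Incorporate predicted yields into the expansion
#'   priority.
#' @param predict_sd SD (percent) of the emulated yield predictor's error.
#' @param seed Seed for the emulated prediction noise.
#' @return List: `expansions` (count until the best route's leaf is
#'   reached), `best_leaf`.
#' @export
toy_route_search <- function(tree, use_yield = TRUE, predict_sd = 10,
                             seed = 1L) {
  stopifnot(inherits(tree, "rxy_route_tree"))
  e <- tree$edges
  pred_yield <- with_local_seed(derive_seed(seed, "route_pred"), {
    pmin(95, pmax(5, e$yield_percent + stats::rnorm(nrow(e), 0, predict_sd)))
  })
  edge_score <- if (use_yield) {
    yield_incorporated_prior(e$template_prior, pred_yield)
  } else {
    e$template_prior
  }
  kids <- split(seq_len(nrow(e)), e$parent)
  target <- best_route_yield(tree)

  # frontier of nodes with their cumulative scores
  frontier_nodes <- 1L
  frontier_scores <- 1
  expansions <- 0L
  repeat {
    i <- which.max(frontier_scores)
    node <- frontier_nodes[i]
    sc <- frontier_scores[i]
    frontier_nodes <- frontier_nodes[-i]
    frontier_scores <- frontier_scores[-i]
    if (node == target) break
    edge_idx <- kids[[as.character(node)]]
    if (!is.null(edge_idx)) {
      expansions <- expansions + 1L
      frontier_nodes <- c(frontier_nodes, e$child[edge_idx])
      frontier_scores <- c(frontier_scores, sc * edge_score[edge_idx])
    }
    if (length(frontier_nodes) == 0L) break
  }
  list(expansions = expansions, best_leaf = target)
}
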