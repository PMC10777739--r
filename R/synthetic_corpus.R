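# Synthetic reaction corpus with known ground truth.
#
# The generator emulates the structure of a multi-condition yield dataset:
# reaction groups that share canonical reactants and products while their
# yields vary with the reagent/solvent/catalyst conditions, 12 long-tailed
# category labels, and a yield distribution skewed toward high yields with a
# low-yield tail. Yields follow an additive model
#   yield = clip(group base + sum(condition effects) + noise, 0, 100)
# whose per-condition effects and noise draws are returned alongside the
# records, so parameter-recovery tests can verify the corpus carries the
# condition-to-yield signal the model is meant to learn.

# Built-in molecule library (valid, RDKit-parseable SMILES). Roles are
# mutually disjoint; reactant and product pools are disjoint so no group is
# an identity reaction.
MOLECULE_LIBRARY <- list(
  reactant = c(
    "CCO", "CCN", "CCCl", "CCBr", "CC(C)O", "CC(C)N", "c1ccccc1",
    "Oc1ccccc1", "Nc1ccccc1", "Brc1ccccc1", "Clc1ccccc1", "CC(=O)O",
    "CC(=O)Cl", "C=CC", "C=CCBr", "OCCO", "OCCN", "NCCN", "c1ccncc1",
    "c1ccoc1", "c1ccsc1", "CCC=O", "CC=O", "OC(=O)c1ccccc1", "NC(C)=O",
    "CNC", "CN(C)C", "CSC", "C#CC", "OCC#N", "CC(=O)C(C)=O", "OCc1ccco1",
    "NCc1ccccc1", "CC(N)C", "CCC(=O)Cl", "C1CC1"
  ),
  product = c(
    "CCOC(=O)c1ccccc1", "CC(=O)Nc1ccccc1", "c1ccc(-c2ccccc2)cc1",
    "CC(O)c1ccccc1", "CCNc1ccccc1", "COc1ccccc1", "CCSc1ccccc1",
    "CC(=O)OCC", "N#Cc1ccccc1", "OCc1ccccc1", "CC(C)Oc1ccccc1",
    "c1ccc(Cc2ccccc2)cc1", "CC(=O)c1ccccc1", "CCC(=O)O", "CCCN", "CCCO",
    "CC(N)=O", "CCOC(=O)CC", "CC(=O)NC", "c1ccc(Oc2ccccc2)cc1",
    "c1ccc(Nc2ccccc2)cc1", "CCc1ccccc1", "CC(O)CN", "OCCOc1ccccc1",
    "CN(C)c1ccccc1", "C=Cc1ccccc1", "CC(C)(C)O", "CC1CCCCC1",
    "O=Cc1ccccc1", "CC(C)C(=O)O"
  ),
  # conditions are kept single-fragment so each stays one token-able unit of
  # the middle segment (salts appear in covalent or lone-ion form)
  reagent = c(
    "[Na]O", "[K]O", "O=C(O[Na])O[Na]", "O=C(O[K])O[K]", "CC(C)(C)O[K]",
    "CCN(CC)CC", "CCN(C(C)C)C(C)C", "O=S(Cl)Cl", "CC(=O)OC(C)=O", "[NaH]",
    "[BH4-]", "[AlH4-]", "CC[Mg]Br", "C[Si](C)(C)Cl", "OO",
    "O=S(=O)(O)O", "Cl", "Br", "CCOC(=O)N=NC(=O)OCC",
    "c1ccc(P(c2ccccc2)c2ccccc2)cc1", "O=P(Cl)(Cl)Cl",
    "CC(C)(C)OC(=O)OC(=O)OC(C)(C)C"
  ),
  solvent = c(
    "O", "CO", "CC#N", "C1CCOC1", "CS(C)=O", "CN(C)C=O", "ClCCl",
    "ClC(Cl)Cl", "Cc1ccccc1", "C1CCCCC1", "COCCOC", "CC(C)=O",
    "C1COCCO1", "CCCCO"
  ),
  catalyst = c(
    "[Pd]", "[Pt]", "[Ni]", "[Fe]", "[Cu]", "[Zn]", "[Rh]", "[Ru]",
    "Cl[Pd]Cl", "I[Cu]"
  )
)

# Midpoints used when a corpus pins each record's yield to one bin.
BIN_CENTERS <- c(extremely_low = 15, low = 40, medium = 65, high = 90)

#' Specification of a synthetic reaction corpus
#'
#' @param n_groups Number of reaction groups.
#' @param conditions_per_group Length-2 integer range; each group draws its
#'   member count (condition variants) uniformly from this range.
#' @param n_reagents,n_solvents,n_catalysts Condition catalog sizes per role.
#' @param base_yield_range Percent interval the group base yields span.
#' @param condition_effect_sd SD (percent) of the additive per-condition
#'   yield effects.
#' @param noise_sd SD (percent) of the per-record observation noise.
#' @param n_categories Number of reaction-category labels (default 12).
#' @param long_tail_skew Controls both the low-yield tail of the base-yield
#'   distribution and the imbalance of category sizes (larger = rarer tail
#'   categories and heavier low-yield tail).
#' @param p_catalyst Probability a record's condition set includes a
#'   catalyst.
#' @param deterministic_bins If TRUE, each record's yield class is a
#'   deterministic function of its reagent (four marker reagents map to the
#'   four bins); used to probe fine-tuning recovery.
#' @param ensure_all_categories If TRUE, the first `n_categories` groups get
#'   one category each so no category is empty.
#' @param seed Integer seed; the corpus is a pure function of the spec.
#' @return Object of class `rxy_corpus_spec`.
#' @export
corpus_spec <- function(n_groups = 60,
                        conditions_per_group = c(2L, 6L),
                        n_reagents = 12L, n_solvents = 8L, n_catalysts = 5L,
                        base_yield_range = c(20, 95),
                        condition_effect_sd = 10,
                        noise_sd = 2,
                        n_categories = 12L,
                        long_tail_skew = 1.5,
                        p_catalyst = 0.5,
                        deterministic_bins = FALSE,
                        ensure_all_categories = TRUE,
                        seed = 1L) {
  spec <- list(n_groups = as.integer(n_groups),
               conditions_per_group = as.integer(conditions_per_group),
               n_reagents = as.integer(n_reagents),
               n_solvents = as.integer(n_solvents),
               n_catalysts = as.integer(n_catalysts),
               base_yield_range = as.numeric(base_yield_range),
               condition_effect_sd = as.numeric(condition_effect_sd),
               noise_sd = as.numeric(noise_sd),
               n_categories = as.integer(n_categories),
               long_tail_skew = as.numeric(long_tail_skew),
               p_catalyst = as.numeric(p_catalyst),
               deterministic_bins = isTRUE(deterministic_bins),
               ensure_all_categories = isTRUE(ensure_all_categories),
               seed = as.integer(seed))
  with(spec, {
    if (n_groups < 1L || n_reagents < 1L || n_solvents < 1L || n_catalysts < 1L ||
        n_categories < 1L) {
      rxy_abort("rxy_config_error", "all corpus counts must be positive")
    }
    if (length(conditions_per_group) != 2L || any(conditions_per_group < 1L) ||
        conditions_per_group[1L] > conditions_per_group[2L]) {
      rxy_abort("rxy_config_error", "conditions_per_group must be an increasing positive range")
    }
    if (condition_effect_sd < 0 || noise_sd < 0) {
      rxy_abort("rxy_config_error", "standard deviations must be non-negative")
    }
  })
  class(spec) <- "rxy_corpus_spec"
  spec
}

#' Draw a role-keyed condition catalog
#'
#' Samples reagent, solvent, and catalyst SMILES (canonicalized, disjoint
#' across roles) from the built-in molecule library.
#'
#' @param spec An [corpus_spec()] object.
#' @param seed Seed; defaults to the spec's.
#' @return Named list of character vectors `reagent`, `solvent`, `catalyst`.
#' @export
generate_condition_catalog <- function(spec, seed = spec$seed) {
  sizes <- c(reagent = spec$n_reagents, solvent = spec$n_solvents,
             catalyst = spec$n_catalysts)
  out <- list()
  for (role in names(sizes)) {
    lib <- MOLECULE_LIBRARY[[role]]
    if (sizes[[role]] > length(lib)) {
      rxy_abort("rxy_catalog_error",
                sprintf("requested %d %ss but the library has %d",
                        sizes[[role]], role, length(lib)))
    }
    pick <- with_local_seed(derive_seed(seed, paste0("catalog_", role)),
                            sample(lib, sizes[[role]]))
    out[[role]] <- canonicalize_smiles(pick)
  }
  out
}

# Infer the role of a condition fragment from a catalog (NA if absent).
condition_role <- function(fragment, catalog) {
  for (role in names(catalog)) {
    if (fragment %in% catalog[[role]]) return(role)
  }
  NA_character_
}

#' Generate a synthetic reaction corpus with ground truth
#'
#' See [corpus_spec()] for the yield model. Reaction SMILES come out in
#' canonical form (canonical fragments, lexicographically sorted within each
#' segment).
#'
#' @param spec An [corpus_spec()] object.
#' @return List with `records` (reaction record data.frame, group and
#'   category ids filled), `truth` (list: `effects` per catalog condition,
#'   `records` per-record base/effect/noise decomposition), `catalog`, and
#'   the echoed `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "rxy_corpus_spec"))
  catalog <- generate_condition_catalog(spec)

  reactants <- canonicalize_smiles(MOLECULE_LIBRARY$reactant)
  products <- canonicalize_smiles(MOLECULE_LIBRARY$product)

  with_local_seed(derive_seed(spec$seed, "corpus"), {
    # unique reactant-pair x product keys
    n_try <- spec$n_groups * 4L
    r1 <- sample(reactants, n_try, replace = TRUE)
    r2 <- sample(reactants, n_try, replace = TRUE)
    pr <- sample(products, n_try, replace = TRUE)
    ok <- r1 != r2
    key <- paste(pmin(r1, r2), pmax(r1, r2), pr)
    keep <- which(ok & !duplicated(key))
    if (length(keep) < spec$n_groups) {
      rxy_abort("rxy_catalog_error",
                "molecule library too small for the requested number of groups")
    }
    keep <- keep[seq_len(spec$n_groups)]
    g_r1 <- pmin(r1[keep], r2[keep]); g_r2 <- pmax(r1[keep], r2[keep])
    g_pr <- pr[keep]

    # category labels: weights decay with category id -> long-tailed sizes
    w <- (seq_len(spec$n_categories))^(-spec$long_tail_skew)
    cats <- sample(0:(spec$n_categories - 1L), spec$n_groups, replace = TRUE,
                   prob = w)
    if (spec$ensure_all_categories && spec$n_groups >= spec$n_categories) {
      cats[seq_len(spec$n_categories)] <- 0:(spec$n_categories - 1L)
    }

    # skewed base yields: high-yield bulk, low-yield tail
    lo <- spec$base_yield_range[1L]; hi <- spec$base_yield_range[2L]
    base <- lo + (hi - lo) * stats::rbeta(spec$n_groups, 5, spec$long_tail_skew)

    # additive condition effects
    all_cond <- unlist(catalog, use.names = FALSE)
    roles <- rep(names(catalog), lengths(catalog))
    effects <- stats::rnorm(length(all_cond), 0, spec$condition_effect_sd)
    names(effects) <- all_cond

    markers <- catalog$reagent[seq_len(min(4L, length(catalog$reagent)))]

    rows <- vector("list", spec$n_groups)
    truth_rows <- vector("list", spec$n_groups)
    rid <- 0L
    for (g in seq_len(spec$n_groups)) {
      k <- spec$conditions_per_group[1L] +
        sample.int(spec$conditions_per_group[2L] - spec$conditions_per_group[1L] + 1L, 1L) - 1L
      rs <- sort(c(g_r1[g], g_r2[g]), method = "radix")
      recs <- vector("list", k)
      trs <- vector("list", k)
      for (j in seq_len(k)) {
        rid <- rid + 1L
        if (spec$deterministic_bins) {
          # low-yield markers are rare, mirroring the long-tailed label
          # distribution of curated yield data
          mw <- if (length(markers) == 4L) c(0.08, 0.17, 0.30, 0.45) else NULL
          marker <- sample(markers, 1L, prob = mw)
          conds <- c(marker, sample(catalog$solvent, 1L))
          center <- BIN_CENTERS[[match(marker, markers)]]
          y_raw <- center + stats::runif(1, -5, 5)
          eff_sum <- 0; noise <- 0; b <- center
        } else {
          conds <- c(sample(catalog$reagent, 1L), sample(catalog$solvent, 1L))
          if (stats::runif(1) < spec$p_catalyst) {
            conds <- c(conds, sample(catalog$catalyst, 1L))
          }
          b <- base[g]
          eff_sum <- sum(effects[conds])
          noise <- stats::rnorm(1, 0, spec$noise_sd)
          y_raw <- b + eff_sum + noise
        }
        y <- min(100, max(0, y_raw))
        smi <- paste0(paste(rs, collapse = "."), ">",
                      paste(sort(conds, method = "radix"), collapse = "."),
                      ">", g_pr[g])
        recs[[j]] <- data.frame(record_id = sprintf("R%06d", rid),
                                reaction_smiles = smi,
                                yield_percent = y,
                                group_id = sprintf("G%05d", g),
                                category_id = cats[g],
                                stringsAsFactors = FALSE)
        trs[[j]] <- data.frame(record_id = sprintf("R%06d", rid),
                               base_yield = b, effect_sum = eff_sum,
                               noise = noise, clipped = (y != y_raw),
                               stringsAsFactors = FALSE)
      }
      rows[[g]] <- do.call(rbind, recs)
      truth_rows[[g]] <- do.call(rbind, trs)
    }

    records <- do.call(rbind, rows)
    rownames(records) <- NULL
    truth <- list(
      effects = data.frame(condition_smiles = all_cond, role = roles,
                           effect = unname(effects), stringsAsFactors = FALSE),
      records = do.call(rbind, truth_rows)
    )
    list(records = records, truth = truth, catalog = catalog, spec = spec)
  })
}

#' Write a generated corpus (records + ground-truth sidecars) to a directory
#'
#' @param corpus Result of [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(records = file.path(dir, "corpus.csv"),
             truth = file.path(dir, "ground_truth.csv"),
             effects = file.path(dir, "condition_effects.csv"),
             catalog = file.path(dir, "catalog.csv"))
  write_reaction_table(corpus$records, paths[["records"]])
  utils::write.csv(corpus$truth$records, paths[["truth"]], row.names = FALSE)
  utils::write.csv(corpus$truth$effects, paths[["effects"]], row.names = FALSE)
  cat_df <- data.frame(role = rep(names(corpus$catalog), lengths(corpus$catalog)),
                       condition_smiles = unlist(corpus$catalog, use.names = FALSE),
                       stringsAsFactors = FALSE)
  utils::write.csv(cat_df, paths[["catalog"]], row.names = FALSE)
  invisible(paths)
}

#' Read a condition catalog written by [write_corpus()]
#' @param path catalog.csv path.
#' @return Role-keyed list of condition SMILES.
#' @export
read_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split(df$condition_smiles, df$role)
}
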