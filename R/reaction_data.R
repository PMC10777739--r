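# Reaction representation: `reactants>conditions>products` strings, the regex
# tokenizer, vocabulary, yield bins, reaction groups, stratified splits and
# CSV table I/O.
#
# A set of reaction records is an ordinary data.frame with columns
# record_id, reaction_smiles, yield_percent, group_id, category_id
# (the last two may be NA). Conditions (reagents, solvents, catalysts,
# pooled) occupy the middle `>` segment; roles live in metadata, not in the
# string.

YIELD_BIN_LEVELS <- c("extremely_low", "low", "medium", "high")

# Lower bin edges in percent; high is closed at 100.
YIELD_BIN_BREAKS <- c(0, 30, 50, 80, 100)

RESERVED_TOKENS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")

#' Split a reaction SMILES into its three segments
#'
#' @param reaction_smiles A `reactants>conditions>products` string.
#' @return List with character vectors `reactants`, `conditions`, `products`
#'   (dot-separated fragments, split).
#' @export
split_reaction <- function(reaction_smiles) {
  stopifnot(is.character(reaction_smiles), length(reaction_smiles) == 1L)
  parts <- strsplit(reaction_smiles, ">", fixed = TRUE)[[1L]]
  n_sep <- lengths(regmatches(reaction_smiles, gregexpr(">", reaction_smiles, fixed = TRUE)))
  if (n_sep != 2L) {
    rxy_abort("rxy_parse_error",
              sprintf("reaction SMILES must contain exactly two '>' separators, found %d in '%s'",
                      n_sep, reaction_smiles))
  }
  parts <- c(parts, rep("", 3L - length(parts)))
  seg <- function(s) if (nzchar(s)) strsplit(s, ".", fixed = TRUE)[[1L]] else character(0)
  out <- list(reactants = seg(parts[1L]), conditions = seg(parts[2L]),
              products = seg(parts[3L]))
  if (length(out$reactants) == 0L || length(out$products) == 0L) {
    rxy_abort("rxy_parse_error",
              sprintf("reactant and product segments must be non-empty in '%s'", reaction_smiles))
  }
  out
}

#' Assemble a reaction SMILES from segments
#' @param segments List as returned by [split_reaction()].
#' @return Reaction SMILES string.
#' @export
join_reaction <- function(segments) {
  paste(vapply(segments[c("reactants", "conditions", "products")],
               paste, "", collapse = "."), collapse = ">")
}

.canon_segment <- function(frags, segment, reaction_smiles) {
  if (length(frags) == 0L) return(character(0))
  out <- tryCatch(canonicalize_smiles(frags), rxy_parse_error = function(e) e)
  if (inherits(out, "condition")) {
    rxy_abort("rxy_parse_error",
              sprintf("in %s segment of '%s': %s", segment, reaction_smiles,
                      conditionMessage(out)))
  }
  sort(out, method = "radix")
}

#' Canonicalize a reaction SMILES
#'
#' Each fragment is canonicalized by RDKit's canonical SMILES algorithm, then
#' fragments within each segment are sorted lexicographically (byte order)
#' and dot-joined. The result is the anchor representation used throughout
#' the package; the map is idempotent.
#'
#' @param reaction_smiles Character vector of reaction SMILES.
#' @return Character vector of canonical reaction SMILES.
#' @export
canonicalize_reaction <- function(reaction_smiles) {
  vapply(reaction_smiles, function(r) {
    seg <- split_reaction(r)
    join_reaction(list(
      reactants  = .canon_segment(seg$reactants, "reactant", r),
      conditions = .canon_segment(seg$conditions, "condition", r),
      products   = .canon_segment(seg$products, "product", r)
    ))
  }, "", USE.NAMES = FALSE)
}

# Regex of Schwaller-style SMILES tokenization, extended with the `>`
# separator so a whole reaction string tokenizes in one pass.
SMILES_TOKEN_REGEX <- paste0(
  "\\[[^\\]]+\\]|Br?|Cl?|N|O|S|P|F|I|b|c|n|o|s|p|\\(|\\)|\\.|=|#|-|\\+|",
  "\\\\|/|:|~|@|\\?|>|\\*|\\$|%[0-9]{2}|[0-9]"
)

#' Tokenize a reaction SMILES
#'
#' Lossless regex tokenization: bracket atoms are single tokens, two-letter
#' halogens stay intact, `%nn` ring closures are one token, and every other
#' recognized character is its own token. Joining the tokens reproduces the
#' input exactly.
#'
#' @param reaction_smiles A single SMILES or reaction SMILES string.
#' @return Character vector of tokens.
#' @export
tokenize_reaction <- function(reaction_smiles) {
  stopifnot(is.character(reaction_smiles), length(reaction_smiles) == 1L)
  if (!nzchar(reaction_smiles)) {
    rxy_abort("rxy_tokenize_error", "cannot tokenize an empty string")
  }
  m <- gregexpr(SMILES_TOKEN_REGEX, reaction_smiles, perl = TRUE)[[1L]]
  toks <- regmatches(reaction_smiles, list(m))[[1L]]
  covered <- sum(attr(m, "match.length"))
  if (m[1L] == -1L || covered != nchar(reaction_smiles)) {
    # locate the first byte not covered by any match
    pos <- rep(FALSE, nchar(reaction_smiles))
    if (m[1L] != -1L) {
      for (i in seq_along(m)) {
        pos[seq(m[i], length.out = attr(m, "match.length")[i])] <- TRUE
      }
    }
    bad <- which(!pos)[1L]
    rxy_abort("rxy_tokenize_error",
              sprintf("unrecognized character '%s' at offset %d of '%s'",
                      substr(reaction_smiles, bad, bad), bad, reaction_smiles))
  }
  toks
}

#' Build a token vocabulary from a reaction corpus
#'
#' Ids 1..5 are reserved for `[PAD]`, `[UNK]`, `[CLS]`, `[SEP]`, `[MASK]`;
#' observed tokens follow, ordered by decreasing corpus frequency with
#' lexicographic tie-break, so the vocabulary is a pure function of the
#' corpus.
#'
#' @param corpus Character vector of reaction SMILES.
#' @return Object of class `rxy_vocab`.
#' @export
build_vocabulary <- function(corpus) {
  if (length(corpus) == 0L) {
    rxy_abort("rxy_empty_corpus_error", "vocabulary requires a non-empty corpus")
  }
  toks <- unlist(lapply(corpus, tokenize_reaction), use.names = FALSE)
  tab <- table(toks)
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  tokens <- c(RESERVED_TOKENS, names(tab)[ord])
  vocab <- list(tokens = tokens,
                index = stats::setNames(seq_along(tokens), tokens),
                pad = 1L, unk = 2L, cls = 3L, sep = 4L, mask = 5L)
  class(vocab) <- "rxy_vocab"
  vocab
}

#' @export
print.rxy_vocab <- function(x, ...) {
  cat(sprintf("<rxy_vocab: %d tokens (5 reserved)>\n", length(x$tokens)))
  invisible(x)
}

#' Number of tokens in a vocabulary (including the 5 reserved tokens)
#' @param vocab An `rxy_vocab`.
#' @return Integer size.
#' @export
vocab_size <- function(vocab) length(vocab$tokens)

# Stable content hash of a vocabulary (used in checkpoints).
vocab_hash <- function(vocab) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(vocab$tokens, f, useBytes = TRUE)
  unname(tools::md5sum(f))
}

#' Map tokens to vocabulary ids
#'
#' Unknown tokens map to the `[UNK]` id.
#'
#' @param tokens Character vector of tokens.
#' @param vocab An `rxy_vocab`.
#' @return Integer vector of ids.
#' @export
token_ids <- function(tokens, vocab) {
  ids <- unname(vocab$index[tokens])
  ids[is.na(ids)] <- vocab$unk
  as.integer(ids)
}

#' Token sequence with `[CLS]`/`[SEP]` framing
#'
#' @param reaction_smiles Reaction SMILES string.
#' @param vocab An `rxy_vocab`.
#' @return List with `tokens`, `ids`, and `specials` (indices of special
#'   positions), class `rxy_token_seq`.
#' @export
token_sequence <- function(reaction_smiles, vocab) {
  toks <- tokenize_reaction(reaction_smiles)
  tokens <- c("[CLS]", toks, "[SEP]")
  out <- list(tokens = tokens,
              ids = token_ids(tokens, vocab),
              specials = c(1L, length(tokens)))
  class(out) <- "rxy_token_seq"
  out
}

#' Bin percent yields into the four yield classes
#'
#' Classes: extremely_low `[0,30)`, low `[30,50)`, medium `[50,80)`,
#' high `[80,100]`. Boundaries are left-closed (a 50% yield is medium);
#' the top class includes 100.
#'
#' @param yield_percent Numeric vector in `[0,100]`.
#' @return Factor with levels `extremely_low < low < medium < high`.
#' @export
bin_yield <- function(yield_percent) {
  if (any(is.na(yield_percent)) ||
      any(yield_percent < 0 | yield_percent > 100)) {
    bad <- which(is.na(yield_percent) | yield_percent < 0 | yield_percent > 100)[1L]
    rxy_abort("rxy_range_error",
              sprintf("yield_percent must lie in [0,100]; element %d is %s",
                      bad, format(yield_percent[bad])))
  }
  idx <- findInterval(yield_percent, YIELD_BIN_BREAKS,
                      rightmost.closed = TRUE, left.open = FALSE)
  factor(YIELD_BIN_LEVELS[idx], levels = YIELD_BIN_LEVELS, ordered = TRUE)
}

#' Construct a reaction record table
#'
#' @param reaction_smiles Character vector of reaction SMILES.
#' @param yield_percent Numeric vector in `[0,100]`.
#' @param record_id Optional ids; generated (`R000001`, ...) if missing.
#' @param group_id Optional group ids (NA allowed).
#' @param category_id Optional integer category ids 0-11 (NA allowed).
#' @return data.frame of reaction records.
#' @export
reaction_records <- function(reaction_smiles, yield_percent,
                             record_id = NULL, group_id = NA_character_,
                             category_id = NA_integer_) {
  n <- length(reaction_smiles)
  stopifnot(length(yield_percent) == n)
  if (any(yield_percent < 0 | yield_percent > 100, na.rm = TRUE)) {
    rxy_abort("rxy_range_error", "yield_percent outside [0,100]")
  }
  if (is.null(record_id)) record_id <- sprintf("R%06d", seq_len(n))
  cat_id <- suppressWarnings(as.integer(category_id))
  if (any(!is.na(cat_id) & (cat_id < 0L | cat_id > 11L))) {
    rxy_abort("rxy_range_error", "category_id must be in 0..11 or NA")
  }
  data.frame(record_id = as.character(record_id),
             reaction_smiles = as.character(reaction_smiles),
             yield_percent = as.numeric(yield_percent),
             group_id = rep_len(as.character(group_id), n),
             category_id = rep_len(cat_id, n),
             stringsAsFactors = FALSE)
}

# reactants>>products key of a (canonical) reaction SMILES; the condition
# segment is dropped so the key is invariant under condition changes.
group_key <- function(reaction_smiles) {
  vapply(reaction_smiles, function(r) {
    p <- strsplit(r, ">", fixed = TRUE)[[1L]]
    paste0(p[1L], ">>", if (length(p) >= 3L) p[3L] else "")
  }, "", USE.NAMES = FALSE)
}

#' Partition records into reaction groups
#'
#' A reaction group is the set of records sharing canonical reactants and
#' products; the condition segment is ignored. Records are assumed
#' canonicalized (see [canonicalize_reaction()]).
#'
#' @param records Reaction record data.frame.
#' @return List with `records` (group_id filled, stable ids in order of first
#'   appearance) and `groups` (data.frame: group_id, group_key, size).
#' @export
build_reaction_groups <- function(records) {
  keys <- group_key(records$reaction_smiles)
  first <- !duplicated(keys)
  ids <- stats::setNames(sprintf("G%05d", seq_len(sum(first))), keys[first])
  records$group_id <- unname(ids[keys])
  groups <- data.frame(group_id = unname(ids),
                       group_key = names(ids),
                       size = as.integer(table(keys)[names(ids)]),
                       stringsAsFactors = FALSE)
  list(records = records, groups = groups)
}

# Largest-remainder apportionment of n into parts proportional to ratios.
apportion <- function(n, ratios) {
  q <- n * ratios
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(-(q - base), seq_along(ratios))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Group-stratified train/validation/test split
#'
#' Within every reaction group the members are randomly apportioned to the
#' three splits in the given ratios (largest-remainder rounding), so a group
#' can span splits. Groups with fewer members than splits go entirely to
#' train. Deterministic given `seed`.
#'
#' @param records Reaction record data.frame (canonical SMILES).
#' @param ratios Numeric length-3 `(train, val, test)`; normalized to sum 1.
#' @param seed Integer seed.
#' @return List of data.frames `train`, `val`, `test`.
#' @export
stratified_split <- function(records, ratios = c(8, 1, 1), seed = 1L) {
  if (length(ratios) != 3L || any(!is.finite(ratios)) || any(ratios < 0) ||
      sum(ratios) <= 0) {
    rxy_abort("rxy_config_error", "ratios must be three non-negative numbers with positive sum")
  }
  ratios <- ratios / sum(ratios)
  keys <- group_key(records$reaction_smiles)
  assign_split <- rep("train", nrow(records))
  for (k in unique(keys)) {
    idx <- which(keys == k)
    n <- length(idx)
    if (n < 3L) next  # small groups stay in train
    counts <- apportion(n, ratios)
    perm <- with_local_seed(derive_seed(seed, k), sample.int(n))
    lab <- rep(c("train", "val", "test"), counts)
    assign_split[idx[perm]] <- lab
  }
  list(train = records[assign_split == "train", , drop = FALSE],
       val   = records[assign_split == "val", , drop = FALSE],
       test  = records[assign_split == "test", , drop = FALSE])
}

#' Restrict a test set to reactions from large training groups
#'
#' Keeps the test records whose reaction group has strictly more than
#' `min_size` members in the training set.
#'
#' @param test_records,train_records Reaction record data.frames.
#' @param min_size Integer threshold (strict).
#' @return Filtered test record data.frame.
#' @export
filter_test_by_group_size <- function(test_records, train_records, min_size) {
  train_sizes <- table(group_key(train_records$reaction_smiles))
  keys <- group_key(test_records$reaction_smiles)
  sz <- as.integer(train_sizes[keys])
  sz[is.na(sz)] <- 0L
  test_records[sz > min_size, , drop = FALSE]
}

#' Read a reaction table from CSV
#'
#' Expects header columns `reaction_smiles,yield` with optional `record_id`,
#' `group_id`, `category_id`. Empty optional cells become NA.
#'
#' @param path CSV file path.
#' @return Reaction record data.frame.
#' @export
read_reaction_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("reaction_smiles", "yield")) {
    if (!col %in% names(df)) {
      rxy_abort("rxy_schema_error", sprintf("missing mandatory column '%s' in %s", col, path))
    }
  }
  y <- suppressWarnings(as.numeric(df$yield))
  bad <- which(is.na(y) | y < 0 | y > 100)
  if (length(bad)) {
    if (is.na(suppressWarnings(as.numeric(df$yield[bad[1L]])))) {
      rxy_abort("rxy_parse_error",
                sprintf("row %d: yield '%s' is not a number", bad[1L], df$yield[bad[1L]]))
    }
    rxy_abort("rxy_range_error",
              sprintf("row %d: yield %s outside [0,100]", bad[1L], df$yield[bad[1L]]))
  }
  opt <- function(col, cast = identity) {
    if (!col %in% names(df)) return(NULL)
    v <- df[[col]]
    v[!nzchar(v)] <- NA
    cast(v)
  }
  reaction_records(df$reaction_smiles, y,
                   record_id = opt("record_id"),
                   group_id = opt("group_id") %||% NA_character_,
                   category_id = opt("category_id", as.integer) %||% NA_integer_)
}

#' Write a reaction table to CSV
#'
#' Round-trips through [read_reaction_table()] losslessly; NA optional fields
#' become empty cells.
#'
#' @param records Reaction record data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reaction_table <- function(records, path) {
  out <- data.frame(record_id = records$record_id,
                    reaction_smiles = records$reaction_smiles,
                    yield = sprintf("%.17g", records$yield_percent),
                    group_id = ifelse(is.na(records$group_id), "", records$group_id),
                    category_id = ifelse(is.na(records$category_id), "",
                                         as.character(records$category_id)),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
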