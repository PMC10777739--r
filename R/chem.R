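# Molecule-level cheminformatics primitives.
#
# Canonical SMILES and randomized (alternative atom-order) SMILES come from
# RDKit, driven through a batched helper process so one invocation serves
# thousands of molecules. Canonical forms are memoised per session because the
# corpus re-uses a small molecule library heavily.

rxy_python <- function() {
  opt <- getOption("rxnyield.python", NULL)
  if (!is.null(opt)) return(opt)
  Sys.which("python")[[1L]]
}

.bridge_script <- function() {
  path <- system.file("python", "rdkit_bridge.py", package = "rxnyield")
  if (!nzchar(path)) {
    rxy_abort("rxy_config_error", "rdkit_bridge.py not found in installed package")
  }
  path
}

.bridge_call <- function(mode, lines) {
  if (length(lines) == 0L) return(character(0))
  inp <- tempfile(fileext = ".txt")
  out <- tempfile(fileext = ".txt")
  on.exit(unlink(c(inp, out)))
  writeLines(lines, inp, useBytes = TRUE)
  status <- system2(rxy_python(), c(.bridge_script(), mode, inp, out),
                    stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L) || !file.exists(out)) {
    rxy_abort("rxy_bridge_error",
              sprintf("cheminformatics helper failed (mode '%s', status %s)", mode, status))
  }
  res <- readLines(out, warn = FALSE)
  if (length(res) != length(lines)) {
    rxy_abort("rxy_bridge_error", "cheminformatics helper returned wrong line count")
  }
  res
}

.canon_cache <- function() {
  if (is.null(.rxy_env$canon)) .rxy_env$canon <- new.env(parent = emptyenv())
  .rxy_env$canon
}

#' Canonicalize molecule SMILES
#'
#' Maps each SMILES string to RDKit's canonical form. Results are cached for
#' the session. Unparseable input raises a parse error (default) or yields
#' `NA` with `on_error = "na"`.
#'
#' @param smiles Character vector of molecule SMILES (a dot-joined fragment
#'   set counts as one molecule string).
#' @param on_error `"stop"` or `"na"`.
#' @return Character vector of canonical SMILES.
#' @export
canonicalize_smiles <- function(smiles, on_error = c("stop", "na")) {
  on_error <- match.arg(on_error)
  stopifnot(is.character(smiles))
  cache <- .canon_cache()
  out <- character(length(smiles))
  need <- !vapply(smiles, function(s) !is.na(s) && exists(s, envir = cache, inherits = FALSE),
                  logical(1))
  hit <- which(!need)
  for (i in hit) out[i] <- get(smiles[i], envir = cache)
  if (any(need)) {
    idx <- which(need)
    uniq <- unique(smiles[idx])
    res <- .bridge_call("canon", uniq)
    for (j in seq_along(uniq)) {
      if (!startsWith(res[j], "ERROR:")) {
        assign(uniq[j], res[j], envir = cache)
      }
    }
    lookup <- stats::setNames(res, uniq)
    for (i in idx) {
      r <- lookup[[smiles[i]]]
      if (startsWith(r, "ERROR:")) {
        if (on_error == "stop") {
          rxy_abort("rxy_parse_error",
                    sprintf("cannot parse molecule '%s': %s", smiles[i], sub("^ERROR:", "", r)))
        }
        out[i] <- NA_character_
      } else {
        out[i] <- r
      }
    }
  }
  out
}

#' Randomized SMILES re-serializations of molecules
#'
#' For each request, returns `n` randomized atom-order SMILES of the same
#' molecule (they all canonicalize back to the input). Deterministic in
#' `seed`. All requests go through one helper invocation.
#'
#' @param smiles Character vector of molecule SMILES.
#' @param n Number of randomized forms per molecule (recycled).
#' @param seed Integer seed per molecule (recycled).
#' @return A list (one element per input) of character vectors of length `n`.
#' @export
random_smiles <- function(smiles, n = 1L, seed = 1L) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  n <- rep_len(as.integer(n), length(smiles))
  seed <- rep_len(as.integer(seed), length(smiles))
  lines <- sprintf("%s\t%d\t%d", smiles, n, abs(seed) %% 2147483647L)
  res <- .bridge_call("random", lines)
  lapply(seq_along(res), function(i) {
    if (startsWith(res[i], "ERROR:")) {
      rxy_abort("rxy_parse_error",
                sprintf("cannot parse molecule '%s'", smiles[i]))
    }
    strsplit(res[i], "\t", fixed = TRUE)[[1L]]
  })
}
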