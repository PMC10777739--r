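# Shared internal helpers: error conditions and seeded evaluation.

.rxy_env <- new.env(parent = emptyenv())

rxy_abort <- function(class, message, ...) {
  stop(structure(
    class = c(class, "rxy_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

rxy_warn <- function(message, class = "rxy_warning") {
  warning(structure(
    class = c(class, "rxy_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals never
#' disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    rxy_abort("rxy_config_error", "seed must be a single non-missing number")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a reproducible child seed from a base seed and a stream label.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
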