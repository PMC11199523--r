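#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers never disturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seed from a parent seed and identifiers; keeps every
# per-subject / per-channel draw reproducible under one cohort seed while
# staying inside the 32-bit integer range.
derive_seed <- function(seed, ...) {
  ids <- c(seed, unlist(lapply(list(...), function(z) {
    if (is.character(z)) sum(utf8ToInt(paste(z, collapse = ""))) else as.numeric(z)
  })))
  x <- 0
  for (v in ids) x <- (x * 7919 + (as.numeric(v) %% 2147483647)) %% 2147483647
  as.integer(x %% .Machine$integer.max) + 1L
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
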