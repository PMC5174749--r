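#' @keywords internal
"_PACKAGE"

## Reserved token symbols. PAD is always index 1 and its embedding row is
## frozen at zero; the remaining specials are artificial symbols that are
## never looked up in pretrained tables.
.PAD <- "<PAD>"
.UNK <- "<UNK>"
.ENTITY1 <- "Entity1"
.ENTITY2 <- "Entity2"
.ENTITY_OTHER <- "EntityOther"
.SPECIALS <- c(.PAD, .UNK, .ENTITY1, .ENTITY2, .ENTITY_OTHER)
.PAD_INDEX <- 1L
.UNK_INDEX <- 2L

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions do not disturb user scripts.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

## Derive a stream-specific child seed from a master seed, kept within the
## 32-bit integer range.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream) * 7919L) %% 2147483129L
}

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
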