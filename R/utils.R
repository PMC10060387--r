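# Internal helpers: deterministic 32-bit hashing (FNV-1a) and scoped RNG.

# 32-bit unsigned arithmetic on doubles. Multiplication is split into
# 16-bit halves so intermediate products stay below 2^53.
.mul32 <- function(a, b) {
  lo <- a %% 65536
  hi <- (a - lo) / 65536
  ((b * lo) + ((b * hi) %% 65536) * 65536) %% 4294967296
}

#' @noRd
fnv1a <- function(x, seed = 2166136261) {
  bytes <- utf8ToInt(as.character(x))
  h <- seed
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648) , as.integer(b))
    # restore sign-free value before multiply
    if (h < 0) h <- h + 4294967296
    h <- .mul32(h, 16777619)
  }
  h
}

# Fast deterministic per-integer hash in [0, 1). Vectorised over i.
# Knuth multiplicative hashing on 32 bits.
.hash_frac <- function(i, salt = 0) {
  h <- .mul32((i + salt * 7919) %% 4294967296, 2654435761)
  h <- .mul32(bitwXor(as.integer(h %% 2147483648), 40503L) %% 4294967296 +
                (h >= 2147483648) * 2147483648, 2246822519)
  h / 4294967296
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Seeds the global RNG, evaluates `expr`, and restores the caller's RNG
#' state. All stochastic operations in the package route through this so
#' that seeds compose predictably.
#'
#' @param seed integer seed (`NULL` = leave the RNG alone).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(expr)
}

#' Derive a child seed from a parent seed and a stream label
#'
#' Hashes `(seed, stream)` into an integer below 2^31 so that independent
#' stochastic stages (pool sampling, forest training, query generation)
#' get reproducible, non-colliding seeds from one master seed.
#'
#' @param seed integer master seed.
#' @param stream character label of the consuming stage.
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, stream) {
  as.integer((fnv1a(paste0(seed, ":", stream)) %% 2147483587) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(paste0(...), call. = FALSE)
}
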