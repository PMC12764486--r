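#' @keywords internal
"_PACKAGE"

## Input checking ------------------------------------------------------------

stop2 <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop2(msg)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

## Seed handling -------------------------------------------------------------

#' Evaluate an expression under a local RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state so library code never clobbers user-level
#' reproducibility.
#'
#' @param seed integer seed, or `NULL` to leave the RNG alone.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream label, staying inside
# 32-bit integer range. Deterministic, stable across platforms.
derive_seed <- function(seed, label) {
  h <- digest::digest(list(as.integer(seed), as.character(label)), algo = "xxhash32")
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}

## Small numeric helpers ------------------------------------------------------

clip01 <- function(x) pmin(pmax(x, 0), 1)

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Row-wise softmax of a matrix.
softmax_rows <- function(X) {
  m <- apply(X, 1L, max)
  E <- exp(X - m)
  E / rowSums(E)
}
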