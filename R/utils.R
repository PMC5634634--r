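#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so seeded helpers do not disturb the global random stream. When
#' `seed` is `NULL` the expression runs against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Canonically order a pair of gene identifiers
#'
#' Returns the two id vectors reordered elementwise so the lexicographically
#' smaller id comes first. Uses C-locale string comparison for stability.
#'
#' @param a,b Character vectors of equal length.
#' @return A list with elements `a` and `b`.
#' @keywords internal
canonical_pair <- function(a, b) {
  swap <- as.character(a) > as.character(b)
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

# round-half-away-from-zero (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)
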