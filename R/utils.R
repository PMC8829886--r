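# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the previous
#' RNG state so generators are pure functions of (parameters, seed).
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

# Derive a child seed from a base seed and indices, kept inside 32-bit range.
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in seq_along(idx)) {
    s <- (s * 69069 + 10007 * as.double(idx[i]) + 1) %% 2147483647
  }
  as.integer(s)
}

clip01 <- function(x) pmin(1, pmax(0, x))

col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2L) {
    return(rep(NA_real_, ncol(x)))
  }
  mu <- colMeans(x)
  sqrt(colSums((x - rep(mu, each = n))^2) / (n - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Runs of TRUE in a logical vector -> data.frame(start, end, length) (indices).
runs_of <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    start = starts[keep],
    end = ends[keep],
    length = r$lengths[keep]
  )
}
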