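# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not disturb
#' the caller's random stream. A `NULL` seed evaluates the code as-is.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  code
}

# Deterministic per-stage seed derived from a master seed. Kept < 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 1009) %% 2147483587L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_ <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# k-fold assignment, seeded shuffle; every fold non-empty for k <= n.
make_folds <- function(n, k, seed = NULL) {
  stopifnot(k >= 2, n >= k)
  idx <- with_seed(seed, sample.int(n))
  split(idx, rep_len(seq_len(k), n))
}

# Shoelace area of a planar polygon ring (first vertex need not repeat).
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}
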