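# Internal helpers shared across the package.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded at `seed` and restores the caller's
#' random-number state afterwards, so seeded package functions never
#' perturb the user's simulation stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
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
  expr
}

# Unit l2-normalization; zero vectors stay zero.
l2_normalize <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm > 0) x / nrm else x
}

# Column means/sds as named vectors (sd with n - 1 denominator).
col_sds <- function(x) {
  apply(x, 2L, stats::sd)
}

# Stop unless all block matrices share the same number of rows.
check_aligned <- function(blocks) {
  ns <- vapply(blocks, nrow, integer(1L))
  if (length(unique(ns)) != 1L) {
    stop("all blocks must have the same number of samples (rows)")
  }
  invisible(ns[1L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
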