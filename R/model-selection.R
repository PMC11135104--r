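# Data-driven design matrix from pairwise one-component PLS, and
# coarse-to-fine cross-validated tuning of per-block feature counts.

#' One-component PLS correlation between two blocks
#'
#' Fits a single pair of unit-norm weight vectors maximizing
#' `cov(X1 a, X2 b)` (the rank-1 SVD of `X1' X2`) and returns the Pearson
#' correlation of the two score vectors.
#'
#' @param x1,x2 sample-aligned, standardized matrices.
#' @return Pearson correlation of the first pair of PLS scores.
#' @export
pls_cor <- function(x1, x2) {
  if (nrow(x1) != nrow(x2)) stop("blocks must be sample-aligned")
  M <- crossprod(x1, x2)
  if (all(M == 0)) stop("degenerate zero cross-covariance between blocks")
  sv <- svd(M, nu = 1L, nv = 1L)
  stats::cor(drop(x1 %*% sv$u), drop(x2 %*% sv$v))
}

#' Design matrix from pairwise block correlations
#'
#' Data-block connectivity weights are the pairwise correlations rounded
#' down to one decimal, `c_qj = floor(10 |r_qj|) / 10`; every data block is
#' fully connected (weight 1) to the outcome block.
#'
#' @param r symmetric matrix (or named square matrix) of pairwise
#'   correlations between the Q data blocks.
#' @return `(Q+1) x (Q+1)` symmetric design matrix with zero diagonal and
#'   the outcome block last (named `.outcome`).
#' @export
design_from_correlations <- function(r) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("correlation matrix must be square")
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) stop("correlations must be in [-1, 1]")
  Q <- nrow(r)
  r <- (r + t(r)) / 2   # symmetrize first, so the rule is idempotent
  w <- floor(round(10 * abs(r), 8)) / 10
  C <- matrix(1, Q + 1L, Q + 1L)
  C[seq_len(Q), seq_len(Q)] <- w
  diag(C) <- 0
  nms <- rownames(r) %||% paste0("block", seq_len(Q))
  dimnames(C) <- list(c(nms, ".outcome"), c(nms, ".outcome"))
  C
}

#' Data-driven design matrix for a set of blocks
#'
#' Convenience wrapper: standardizes the blocks (optional), computes all
#' pairwise [pls_cor()] values and applies [design_from_correlations()].
#'
#' @param blocks named list of sample-aligned matrices.
#' @param scale center/scale the blocks first (default `TRUE`).
#' @return `(Q+1) x (Q+1)` design matrix, outcome last.
#' @export
build_design <- function(blocks, scale = TRUE) {
  Q <- length(blocks)
  if (scale) blocks <- lapply(blocks, function(b) center_scale(b)$x)
  r <- diag(1, Q)
  dimnames(r) <- list(names(blocks), names(blocks))
  if (Q > 1L) {
    for (q in seq_len(Q - 1L)) {
      for (j in seq(q + 1L, Q)) {
        r[q, j] <- r[j, q] <- pls_cor(blocks[[q]], blocks[[j]])
      }
    }
  }
  design_from_correlations(r)
}

#' Default number of components
#'
#' `K - 1` components are used for `K` classes unless overridden.
#'
#' @param K number of classes (`K >= 2`).
#' @param override optional explicit component count.
#' @return Integer component count.
#' @export
choose_ncomp <- function(K, override = NULL) {
  if (K < 2L) stop("K must be at least 2")
  if (!is.null(override)) {
    message("using ncomp override = ", override)
    return(as.integer(override))
  }
  as.integer(K - 1L)
}

# Stratified fold assignment: integer fold id per sample, seeded.
stratified_folds <- function(labels, folds, seed) {
  labels <- as.factor(labels)
  if (any(table(labels) < folds)) stop("every class needs at least 'folds' samples")
  fold <- integer(length(labels))
  with_seed(seed, {
    for (k in levels(labels)) {
      idx <- which(labels == k)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold
}

# Fit on a training subset and predict a test subset through the full
# classification path (scaling inside sgcca, centroids, weighted vote).
fit_predict_split <- function(blocks, labels, train, test, keepX, ncomp, C,
                              ...) {
  tr_blocks <- lapply(blocks, function(b) b[train, , drop = FALSE])
  te_blocks <- lapply(blocks, function(b) b[test, , drop = FALSE])
  model <- sgcca(tr_blocks, labels[train], keepX = keepX, ncomp = ncomp,
                 C = C, scale = TRUE, ...)
  pred <- predict(model, te_blocks)
  list(model = model, prediction = pred,
       metrics = performance_metrics(labels[test], pred$class))
}

#' Repeated cross-validated misclassification error
#'
#' Stratified `folds`-fold cross-validation repeated `repeats` times; each
#' held-out fold is predicted through the full classification path
#' (per-block centroid distance fused by weighted vote) and the overall
#' misclassification rates are averaged.
#'
#' @param blocks named list of samples-by-features matrices.
#' @param labels class vector.
#' @param keepX per-block, per-component feature counts (see [sgcca()]).
#' @param ncomp number of components.
#' @param C optional design matrix (computed once from the full data when
#'   `NULL`).
#' @param folds,repeats cross-validation geometry (default 5 x 5).
#' @param seed integer seed; repeat r uses `seed + r - 1` for its fold
#'   assignment.
#' @return Mean overall misclassification error.
#' @export
cv_error <- function(blocks, labels, keepX, ncomp, C = NULL, folds = 5L,
                     repeats = 5L, seed = 1L) {
  labels <- as.factor(labels)
  if (is.null(C)) C <- build_design(blocks)
  errs <- numeric(0L)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(labels, folds, seed + r - 1L)
    for (f in seq_len(folds)) {
      test <- which(fold == f)
      train <- which(fold != f)
      fp <- fit_predict_split(blocks, labels, train, test, keepX, ncomp, C)
      errs <- c(errs, 1 - fp$metrics$accuracy)
    }
  }
  mean(errs)
}

#' Coarse-to-fine tuning of per-block feature counts
#'
#' Components are tuned sequentially (component 1 with later components
#' absent, then frozen). Within a component, blocks are scanned in turn
#' over the candidate grid while the other blocks stay at their current
#' value; the winner (ties toward the smallest count) is then refined with
#' step halving around it until the step reaches 1 or the winner stops
#' moving.
#'
#' @inheritParams cv_error
#' @param grid integer vector of candidate feature counts (clipped to each
#'   block's feature count).
#' @return List of class `"sgcca_tuning"` with `keepX` (`ncomp x Q`
#'   matrix), `surface` (data frame of every evaluated point: component,
#'   block, value, error) and `seed`.
#' @export
tune_keepX <- function(blocks, labels, grid, ncomp = NULL, C = NULL,
                       folds = 5L, repeats = 5L, seed = 1L) {
  if (length(grid) == 0L) stop("empty grid")
  labels <- as.factor(labels)
  if (is.null(ncomp)) ncomp <- choose_ncomp(nlevels(labels))
  if (is.null(C)) C <- build_design(blocks)
  Q <- length(blocks)
  p_q <- vapply(blocks, ncol, integer(1L))
  surface <- data.frame(component = integer(0L), block = character(0L),
                        value = integer(0L), error = numeric(0L))
  keepX <- matrix(NA_integer_, ncomp, Q, dimnames = list(NULL, names(blocks)))

  eval_point <- function(h, q, v, current) {
    current[h, q] <- v
    err <- cv_error(blocks, labels, keepX = current[seq_len(h), , drop = FALSE],
                    ncomp = h, C = C, folds = folds, repeats = repeats,
                    seed = seed)
    surface <<- rbind(surface, data.frame(component = h, block = names(blocks)[q],
                                          value = v, error = err))
    err
  }

  for (h in seq_len(ncomp)) {
    keepX[h, ] <- pmin(max(grid), p_q)   # starting point for the sweep
    for (q in seq_len(Q)) {
      cand <- sort(unique(pmin(grid, p_q[q])))
      errs <- vapply(cand, function(v) eval_point(h, q, v, keepX), numeric(1L))
      best <- cand[order(errs, cand)][1L]   # ties toward the sparser model
      step <- if (length(cand) > 1L) max(diff(cand)) else 0L
      while (step > 0L) {
        step <- max(1L, step %/% 2L)
        around <- unique(pmax(1L, pmin(p_q[q], c(best - step, best + step))))
        around <- setdiff(around, surface$value[surface$component == h &
                                                  surface$block == names(blocks)[q]])
        if (length(around)) {
          e2 <- vapply(around, function(v) eval_point(h, q, v, keepX), numeric(1L))
          pool_v <- c(best, around)
          pool_e <- c(min(errs), e2)
          new_best <- pool_v[order(pool_e, pool_v)][1L]
          errs <- c(errs, e2)
        } else {
          new_best <- best
        }
        if (step == 1L || new_best == best) { best <- new_best; break }
        best <- new_best
      }
      keepX[h, q] <- best
    }
  }
  structure(list(keepX = keepX, surface = surface, seed = as.integer(seed)),
            class = "sgcca_tuning")
}

#' @export
print.sgcca_tuning <- function(x, ...) {
  cat("sGCCA sparsity tuning (", nrow(x$surface), " CV evaluations)\n", sep = "")
  cat("chosen keepX:\n")
  print(x$keepX)
  invisible(x)
}
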