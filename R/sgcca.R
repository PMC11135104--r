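# Supervised sparse generalized CCA. For Q standardized data blocks X^(q)
# and a centered class-indicator block Y, each component h maximizes
#
#   sum_{q != j} c_qj cov(X^(q) a^(q), X^(j) a^(j)),   ||a^(q)||_2 = 1,
#
# with sparsity imposed on the data-block loadings by soft-thresholding to
# a fixed cardinality keepX, and components made orthogonal within a block
# by regression deflation.

#' Class-indicator (dummy) outcome matrix
#'
#' @param labels class vector (factor or character); class order is the
#'   factor level order, or first appearance for character input.
#' @return List with `y` (n x K 0/1 matrix), `y_centered` (column-centered
#'   copy used in fitting) and `classes`.
#' @export
dummy_matrix <- function(labels) {
  if (!is.factor(labels)) labels <- factor(labels, levels = unique(labels))
  labels <- droplevels(labels)
  K <- nlevels(labels)
  if (K < 2L) stop("need at least 2 classes")
  y <- matrix(0, length(labels), K, dimnames = list(names(labels), levels(labels)))
  y[cbind(seq_along(labels), as.integer(labels))] <- 1
  list(y = y, y_centered = sweep(y, 2L, colMeans(y), "-"),
       classes = levels(labels))
}

#' Soft-threshold a vector to a fixed cardinality
#'
#' Shrinks by the `(k+1)`-th largest absolute entry (tau = 0 when
#' `k = length(z)`): the output is proportional to
#' `sign(z) * max(|z| - tau, 0)`, l2-normalized, with exactly `k` nonzero
#' entries in the absence of ties at the threshold (ties are broken toward
#' the lowest feature index).
#'
#' @param z numeric vector.
#' @param k number of entries to keep, `1 <= k <= length(z)`.
#' @return Unit-norm sparse vector (all-zero, flagged with attribute
#'   `degenerate`, when `z` is all zero).
#' @export
soft_threshold_k <- function(z, k) {
  p <- length(z)
  if (k < 1L || k > p) stop("k must be in [1, length(z)]")
  if (all(z == 0)) {
    return(structure(numeric(p), degenerate = TRUE))
  }
  if (k == p) return(l2_normalize(z))
  ord <- order(-abs(z), seq_len(p))   # ties toward lowest index
  tau <- abs(z[ord[k + 1L]])
  out <- numeric(p)
  sel <- ord[seq_len(k)]
  out[sel] <- sign(z[sel]) * pmax(abs(z[sel]) - tau, 0)
  if (all(out == 0)) {
    # every retained entry tied with the threshold
    return(structure(numeric(p), degenerate = TRUE))
  }
  l2_normalize(out)
}

#' Design-weighted sum of score covariances
#'
#' The sGCCA objective: sum over unordered block pairs `q != j` of
#' `c_qj * cov(X^(q) a^(q), X^(j) a^(j))` (covariance denominator `n - 1`).
#'
#' @param blocks list of sample-aligned matrices; the outcome block, if
#'   any, is simply one of them.
#' @param loadings list of loading vectors, one per block.
#' @param C symmetric design matrix (zero diagonal) over the same blocks.
#' @return Scalar objective value.
#' @export
sgcca_objective <- function(blocks, loadings, C) {
  B <- length(blocks)
  if (length(loadings) != B || nrow(C) != B || ncol(C) != B) {
    stop("blocks, loadings and C must agree in size")
  }
  scores <- lapply(seq_len(B), function(q) drop(blocks[[q]] %*% loadings[[q]]))
  val <- 0
  for (q in seq_len(B - 1L)) {
    for (j in seq((q + 1L), B)) {
      if (C[q, j] != 0) {
        val <- val + C[q, j] * stats::cov(scores[[q]], scores[[j]])
      }
    }
  }
  val
}

# One component of the block-coordinate ascent. `blocks` are the Q data
# blocks (already deflated h - 1 times), `yc` the (deflated) centered
# dummy block; C is (Q+1) x (Q+1) with the outcome last. Returns loadings,
# scores, the objective trace (one value per sweep) and a convergence flag.
fit_component <- function(blocks, yc, C, keepX, tol = 1e-6, max_iter = 100L) {
  Q <- length(blocks)
  n <- nrow(yc)
  all_blocks <- c(blocks, list(.outcome = yc))
  a <- lapply(all_blocks, function(x) svd(x, nu = 0L, nv = 1L)$v[, 1L])
  scores <- lapply(seq_len(Q + 1L), function(q) drop(all_blocks[[q]] %*% a[[q]]))
  # refine the outcome init from the data-block scores, so the first
  # sparse data-block update is steered by class structure rather than by
  # the arbitrary orientation of the dummy block's singular vector
  zy <- drop(crossprod(yc, Reduce(`+`, lapply(seq_len(Q), function(j)
    C[Q + 1L, j] * scores[[j]]))))
  if (any(zy != 0)) {
    a[[Q + 1L]] <- l2_normalize(zy)
    scores[[Q + 1L]] <- drop(yc %*% a[[Q + 1L]])
  }
  obj_trace <- numeric(0L)
  converged <- FALSE
  degenerate <- FALSE
  for (iter in seq_len(max_iter)) {
    a_old <- a
    for (q in seq_len(Q + 1L)) {
      target <- numeric(n)
      for (j in seq_len(Q + 1L)) {
        if (j != q && C[q, j] != 0) target <- target + C[q, j] * scores[[j]]
      }
      z <- drop(crossprod(all_blocks[[q]], target))
      if (q <= Q) {
        cand <- soft_threshold_k(z, keepX[q])
        if (isTRUE(attr(cand, "degenerate"))) degenerate <- TRUE
        # monotone-ascent safeguard: the objective is linear in this
        # block's loading with gradient z, so accept the soft-thresholded
        # candidate only if it does not lower the objective. The first
        # sweep always accepts (the dense SVD warm start is not feasible
        # under the cardinality constraint).
        if (iter == 1L || sum(cand * z) >= sum(a[[q]] * z) - 1e-12) {
          a[[q]] <- cand
        }
      } else {
        a[[q]] <- if (all(z == 0)) { degenerate <- TRUE; z } else l2_normalize(z)
      }
      scores[[q]] <- drop(all_blocks[[q]] %*% a[[q]])
    }
    obj_trace <- c(obj_trace, sgcca_objective(all_blocks, a, C))
    delta <- max(vapply(seq_len(Q + 1L), function(q) {
      min(max(abs(a[[q]] - a_old[[q]])), max(abs(a[[q]] + a_old[[q]])))
    }, numeric(1L)))
    if (delta < tol) { converged <- TRUE; break }
  }
  # canonical global sign: largest-|entry| of the outcome loading positive
  ay <- a[[Q + 1L]]
  if (any(ay != 0) && ay[which.max(abs(ay))] < 0) {
    a <- lapply(a, function(v) -v)
    scores <- lapply(scores, function(s) -s)
  }
  list(loadings = a[seq_len(Q)], loading_y = a[[Q + 1L]],
       scores = scores[seq_len(Q)], score_y = scores[[Q + 1L]],
       objective = obj_trace, converged = converged, degenerate = degenerate)
}

#' Regression deflation of a block by a score vector
#'
#' @param x matrix to deflate.
#' @param t score vector with positive norm.
#' @return List with `x` (deflated matrix, orthogonal to `t`) and `b` (the
#'   regression row vector `(t't)^-1 t'X` needed to replay the deflation on
#'   new data).
#' @export
deflate <- function(x, t) {
  ss <- sum(t^2)
  if (ss <= 0) stop("cannot deflate by a zero score vector")
  b <- drop(crossprod(t, x)) / ss
  list(x = x - tcrossprod(t, b), b = b)
}

# Normalize a keepX argument to an H x Q matrix with block names.
normalize_keepX <- function(keepX, H, block_names, p_q) {
  Q <- length(block_names)
  if (is.null(keepX)) keepX <- p_q
  if (is.list(keepX)) {
    if (!all(block_names %in% names(keepX))) stop("keepX list must name every block")
    keepX <- vapply(block_names, function(b) rep_len(keepX[[b]], H), numeric(H))
    keepX <- matrix(keepX, H, Q, dimnames = list(NULL, block_names))
  } else if (is.matrix(keepX)) {
    if (ncol(keepX) != Q) stop("keepX matrix must have one column per block")
    if (nrow(keepX) != H) keepX <- matrix(rep_len(t(keepX), H * Q), H, Q, byrow = TRUE)
    colnames(keepX) <- block_names
  } else {
    keepX <- matrix(rep_len(keepX, Q), H, Q, byrow = TRUE,
                    dimnames = list(NULL, block_names))
  }
  keepX <- matrix(as.integer(keepX), H, Q, dimnames = list(NULL, block_names))
  for (q in seq_len(Q)) {
    if (any(keepX[, q] < 1L) || any(keepX[, q] > p_q[q])) {
      stop(sprintf("keepX for block '%s' must be in [1, %d]", block_names[q], p_q[q]))
    }
  }
  keepX
}

#' Fit a supervised sparse generalized CCA model
#'
#' Fits `ncomp` components by block-coordinate ascent with
#' soft-thresholding to `keepX` features per block and component, deflating
#' each data block (and the outcome block) by its own scores between
#' components. Stores everything needed for out-of-sample projection and
#' classification: scaling parameters, deflation coefficients, per-block
#' class centroids in score space and score-outcome correlation weights.
#'
#' @param blocks named list of samples-by-features matrices (same sample
#'   order; sample IDs as row names recommended).
#' @param labels class vector of length n (factor or character).
#' @param keepX number of features to retain per block and component:
#'   a single number, a named list (one value or `ncomp` values per
#'   block), or an `ncomp x Q` matrix. `NULL` keeps all features.
#' @param ncomp number of components `H` (default `K - 1`).
#' @param C optional `(Q+1) x (Q+1)` design matrix, outcome block last. By
#'   default it is built data-driven from pairwise one-component PLS
#'   correlations via [design_from_correlations()], with outcome links 1.
#' @param scale if `TRUE` (default) each block is centered and scaled to
#'   unit column variance; the statistics are stored for prediction.
#' @param tol convergence tolerance on the loading max-change (up to a
#'   global sign flip).
#' @param max_iter maximum block-coordinate sweeps per component.
#' @return An object of class `"sgcca"`.
#' @seealso [predict.sgcca()], [tune_keepX()], [consensus_fit()]
#' @export
sgcca <- function(blocks, labels, keepX = NULL, ncomp = NULL, C = NULL,
                  scale = TRUE, tol = 1e-6, max_iter = 100L) {
  if (is.null(names(blocks)) || any(!nzchar(names(blocks)))) {
    stop("'blocks' must be a named list")
  }
  n <- check_aligned(blocks)
  if (length(labels) != n) stop("labels must match the number of samples")
  blocks <- lapply(blocks, function(b) {
    if (is.null(colnames(b))) colnames(b) <- paste0("V", seq_len(ncol(b)))
    b
  })
  dm <- dummy_matrix(labels)
  K <- length(dm$classes)
  H <- as.integer(ncomp %||% choose_ncomp(K))
  if (H < 1L) stop("ncomp must be at least 1")
  Q <- length(blocks)
  p_q <- vapply(blocks, ncol, integer(1L))
  keepX <- normalize_keepX(keepX, H, names(blocks), p_q)

  scaling <- NULL
  if (scale) {
    scaled <- lapply(blocks, center_scale)
    blocks_s <- lapply(scaled, `[[`, "x")
    scaling <- lapply(scaled, `[[`, "params")
  } else {
    blocks_s <- blocks
  }

  if (is.null(C)) {
    C <- build_design(blocks_s, scale = FALSE)
  }
  if (nrow(C) != Q + 1L || ncol(C) != Q + 1L) {
    stop("C must be (Q+1) x (Q+1) with the outcome block last")
  }

  loadings <- lapply(blocks_s, function(b)
    matrix(0, ncol(b), H, dimnames = list(colnames(b), NULL)))
  loadings_y <- matrix(0, K, H, dimnames = list(dm$classes, NULL))
  scores <- lapply(blocks_s, function(b) matrix(0, n, H, dimnames = list(rownames(b), NULL)))
  scores_y <- matrix(0, n, H)
  defl <- lapply(blocks_s, function(b) matrix(0, H, ncol(b)))
  defl_y <- matrix(0, H, K)
  objective <- vector("list", H)
  converged <- logical(H)

  cur <- blocks_s
  cur_y <- dm$y_centered
  for (h in seq_len(H)) {
    fc <- fit_component(cur, cur_y, C, keepX[h, ], tol = tol, max_iter = max_iter)
    if (!fc$converged) {
      warning(sprintf("component %d did not converge in %d iterations", h, max_iter))
    }
    for (q in seq_len(Q)) {
      loadings[[q]][, h] <- fc$loadings[[q]]
      scores[[q]][, h] <- fc$scores[[q]]
      if (any(fc$scores[[q]] != 0)) {
        d <- deflate(cur[[q]], fc$scores[[q]])
        cur[[q]] <- d$x
        defl[[q]][h, ] <- d$b
      }
    }
    loadings_y[, h] <- fc$loading_y
    scores_y[, h] <- fc$score_y
    if (any(fc$score_y != 0)) {
      dy <- deflate(cur_y, fc$score_y)
      cur_y <- dy$x
      defl_y[h, ] <- dy$b
    }
    objective[[h]] <- fc$objective
    converged[h] <- fc$converged
  }

  model <- structure(list(
    loadings = loadings, loadings_y = loadings_y,
    scores = scores, scores_y = scores_y,
    defl = defl, defl_y = defl_y,
    scaling = scaling, C = C, keepX = keepX, ncomp = H,
    classes = dm$classes, labels = factor(labels, levels = dm$classes),
    y_centered = dm$y_centered,
    objective = objective, converged = converged,
    block_names = names(blocks), call = match.call()
  ), class = "sgcca")
  model$centroids <- lapply(model$scores, function(s) class_centroids(s, model$labels))
  model$weights <- block_weights(model)
  model
}

#' Project new samples onto a fitted model's components
#'
#' Applies the training standardization, then for each component computes
#' the score `t_h = X a_h` and deflates with the training regression
#' coefficients, exactly replaying the fit-time sequence.
#'
#' @param model fitted [sgcca()] object.
#' @param new_blocks named list of raw matrices with the training feature
#'   sets.
#' @return Named list of `n_new x H` score matrices.
#' @export
sgcca_transform <- function(model, new_blocks) {
  missing <- setdiff(model$block_names, names(new_blocks))
  if (length(missing)) stop("missing block(s): ", paste(missing, collapse = ", "))
  out <- list()
  for (q in model$block_names) {
    x <- new_blocks[[q]]
    feats <- rownames(model$loadings[[q]])
    if (!all(feats %in% colnames(x))) stop("missing features in block ", q)
    x <- x[, feats, drop = FALSE]
    if (!is.null(model$scaling)) x <- apply_scaling(x, model$scaling[[q]])
    tt <- matrix(0, nrow(x), model$ncomp, dimnames = list(rownames(x), NULL))
    for (h in seq_len(model$ncomp)) {
      tt[, h] <- drop(x %*% model$loadings[[q]][, h])
      x <- x - tcrossprod(tt[, h], model$defl[[q]][h, ])
    }
    out[[q]] <- tt
  }
  out
}
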