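# S3 methods for fitted sgcca models.

#' @export
print.sgcca <- function(x, ...) {
  cat("Supervised sparse generalized CCA\n")
  cat(sprintf("  %d block(s), %d component(s), %d classes (%s)\n",
              length(x$block_names), x$ncomp, length(x$classes),
              paste(x$classes, collapse = ", ")))
  for (q in x$block_names) {
    nz <- colSums(x$loadings[[q]] != 0)
    cat(sprintf("  %-10s %5d features; selected per component: %s\n", q,
                nrow(x$loadings[[q]]), paste(nz, collapse = ", ")))
  }
  cat("  block weights:",
      paste(sprintf("%s=%.3f", x$block_names, x$weights), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.sgcca <- function(object, ...) {
  sel <- selected_features(object)
  res <- list(model = object, selected = sel,
              final_objective = vapply(object$objective, function(o) o[length(o)],
                                       numeric(1L)),
              iterations = vapply(object$objective, length, integer(1L)))
  class(res) <- "summary.sgcca"
  res
}

#' @export
print.summary.sgcca <- function(x, ...) {
  print(x$model)
  cat("  objective at convergence:",
      paste(sprintf("%.4f", x$final_objective), collapse = ", "),
      sprintf("(%s sweeps)\n", paste(x$iterations, collapse = ", ")))
  cat("  selected features:", nrow(x$selected), "block-component-feature rows\n")
  invisible(x)
}

#' Extract sparse loading vectors
#'
#' @param object fitted [sgcca()] model.
#' @param block block name (default: all blocks).
#' @param ... unused.
#' @return Named list of `p x H` loading matrices (or a single matrix when
#'   one block is requested).
#' @export
coef.sgcca <- function(object, block = NULL, ...) {
  if (is.null(block)) return(object$loadings)
  object$loadings[[block]]
}

#' Selected (nonzero-loading) features of a fitted model
#'
#' @param model fitted [sgcca()] model.
#' @return Data frame with `block`, `component`, `feature`, `loading`.
#' @export
selected_features <- function(model) {
  out <- lapply(model$block_names, function(q) {
    L <- model$loadings[[q]]
    do.call(rbind, lapply(seq_len(ncol(L)), function(h) {
      nz <- which(L[, h] != 0)
      if (!length(nz)) return(NULL)
      data.frame(block = q, component = h, feature = rownames(L)[nz],
                 loading = unname(L[nz, h]), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Predict classes for new multi-omics samples
#'
#' Projects each block onto the fitted components, classifies per block by
#' nearest class centroid, and fuses the per-block votes by weighted vote
#' using the training score-outcome correlation weights.
#'
#' @param object fitted [sgcca()] model.
#' @param newdata named list of raw samples-by-features matrices containing
#'   the training features.
#' @param ... unused.
#' @return List of class `"sgcca_prediction"` with `class` (final factor),
#'   `block_class` (per-block votes), `centroid_score` (per-block `n x K`
#'   negative-distance matrices), `scores` (per-block `n x H` projections)
#'   and `weights`.
#' @export
predict.sgcca <- function(object, newdata, ...) {
  scores <- sgcca_transform(object, newdata)
  bp <- lapply(stats::setNames(object$block_names, object$block_names),
               function(q) predict_block(object$centroids[[q]], scores[[q]]))
  block_class <- lapply(bp, `[[`, "class")
  final <- weighted_vote(block_class, object$weights)
  structure(list(class = final, block_class = block_class,
                 centroid_score = lapply(bp, `[[`, "score"),
                 scores = scores, weights = object$weights),
            class = "sgcca_prediction")
}

#' @export
print.sgcca_prediction <- function(x, ...) {
  cat("sgcca prediction for", length(x$class), "samples\n")
  print(table(x$class))
  invisible(x)
}

#' Plot training samples in component space
#'
#' Scatter of the first two component scores per block (or the single
#' component against sample index when `ncomp = 1`), colored by class.
#'
#' @param x fitted [sgcca()] model.
#' @param blocks blocks to plot (default all).
#' @param ... passed to [graphics::plot()].
#' @export
plot.sgcca <- function(x, blocks = x$block_names, ...) {
  old <- graphics::par(mfrow = c(1, length(blocks)))
  on.exit(graphics::par(old))
  cols <- seq_along(x$classes) + 1L
  for (q in blocks) {
    s <- x$scores[[q]]
    if (ncol(s) >= 2L) {
      graphics::plot(s[, 1L], s[, 2L], col = cols[as.integer(x$labels)],
                     pch = 19, xlab = "component 1", ylab = "component 2",
                     main = q, ...)
    } else {
      graphics::plot(seq_len(nrow(s)), s[, 1L],
                     col = cols[as.integer(x$labels)], pch = 19,
                     xlab = "sample", ylab = "component 1", main = q, ...)
    }
  }
  graphics::legend("topright", legend = x$classes, col = cols, pch = 19,
                   cex = 0.8)
  invisible(x)
}

#' Serialize a fitted model to a JSON bundle
#'
#' Writes block names, feature names, loadings, deflation coefficients,
#' scaling parameters, centroids and weights to a single JSON file that
#' [read_sgcca()] can restore.
#'
#' @param model fitted [sgcca()] model.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_sgcca <- function(model, path) {
  payload <- list(
    block_names = model$block_names, classes = model$classes,
    ncomp = model$ncomp, keepX = model$keepX, C = model$C,
    loadings = lapply(model$loadings, function(L)
      list(features = rownames(L), values = unname(L))),
    loadings_y = unname(model$loadings_y),
    defl = lapply(model$defl, unname), defl_y = unname(model$defl_y),
    scaling = model$scaling,
    centroids = lapply(model$centroids, function(m)
      list(classes = rownames(m), values = unname(m))),
    weights = as.list(model$weights)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a model written by [write_sgcca()]
#'
#' The restored object supports projection and prediction
#' ([sgcca_transform()], [predict.sgcca()]); training scores and objective
#' traces are not serialized.
#'
#' @param path JSON file path.
#' @return An `sgcca` object.
#' @export
read_sgcca <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  loadings <- lapply(pl$loadings, function(L) {
    m <- as.matrix(L$values)
    rownames(m) <- L$features
    m
  })
  centroids <- lapply(pl$centroids, function(cm) {
    m <- as.matrix(cm$values)
    rownames(m) <- cm$classes
    m
  })
  scaling <- if (is.null(pl$scaling)) NULL else
    lapply(pl$scaling, function(s) list(center = unlist(s$center),
                                        scale = unlist(s$scale)))
  structure(list(loadings = loadings, loadings_y = as.matrix(pl$loadings_y),
                 defl = lapply(pl$defl, as.matrix), defl_y = as.matrix(pl$defl_y),
                 scaling = scaling, C = as.matrix(pl$C),
                 keepX = as.matrix(pl$keepX), ncomp = pl$ncomp,
                 classes = pl$classes, block_names = pl$block_names,
                 centroids = centroids, weights = unlist(pl$weights)),
            class = "sgcca")
}
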