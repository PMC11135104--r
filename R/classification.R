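# Centroid-distance prediction per block, weighted-vote fusion and
# performance metrics (accuracy/precision/recall/F1, one-vs-rest AUC).

#' Per-class centroids in component-score space
#'
#' @param scores `n x H` score matrix.
#' @param labels class vector of length n.
#' @return `K x H` matrix of class mean scores.
#' @export
class_centroids <- function(scores, labels) {
  labels <- as.factor(labels)
  if (any(tabulate(labels, nlevels(labels)) == 0L)) stop("empty class")
  ctr <- rowsum(scores, labels) / as.vector(table(labels))
  rownames(ctr) <- levels(labels)
  ctr
}

#' Centroid-distance prediction for one block
#'
#' Assigns each sample the class of the nearest centroid (Euclidean
#' distance in score space); ties are broken by class order. The per-class
#' continuous score (used for ROC) is the negative distance.
#'
#' @param centroids `K x H` centroid matrix from [class_centroids()].
#' @param scores `n x H` score matrix.
#' @return List with `class` (factor) and `score` (`n x K` matrix of
#'   negative distances).
#' @export
predict_block <- function(centroids, scores) {
  if (ncol(centroids) != ncol(scores)) stop("component dimension mismatch")
  K <- nrow(centroids)
  d2 <- matrix(0, nrow(scores), K, dimnames = list(rownames(scores), rownames(centroids)))
  for (k in seq_len(K)) {
    d2[, k] <- rowSums(sweep(scores, 2L, centroids[k, ], "-")^2)
  }
  cls <- factor(rownames(centroids)[apply(d2, 1L, which.min)],
                levels = rownames(centroids))
  list(class = cls, score = -sqrt(d2))
}

#' Score-outcome correlation weights per block
#'
#' The weight of block q is the mean over components of the largest
#' absolute Pearson correlation between that block's training score vector
#' and the centered dummy-outcome columns.
#'
#' @param model fitted [sgcca()] object.
#' @return Named numeric vector of weights in `[0, 1]`.
#' @export
block_weights <- function(model) {
  yc <- model$y_centered
  vapply(model$block_names, function(q) {
    s <- model$scores[[q]]
    mean(vapply(seq_len(ncol(s)), function(h) {
      t_h <- s[, h]
      if (stats::sd(t_h) == 0) return(0)
      max(abs(stats::cor(t_h, yc)))
    }, numeric(1L)))
  }, numeric(1L))
}

#' Combine per-block votes by weighted vote
#'
#' Each block votes for its predicted class with its weight; the class
#' with the largest summed weight wins. Ties go to the class voted by the
#' highest-weight block among the tied classes (block order breaks weight
#' ties).
#'
#' @param block_classes named list (or data frame) of per-block predicted
#'   class vectors, all with the same class levels.
#' @param weights numeric vector of block weights, same order as
#'   `block_classes`.
#' @return Factor of final predicted classes.
#' @export
weighted_vote <- function(block_classes, weights) {
  block_classes <- lapply(block_classes, as.factor)
  if (length(block_classes) < 1L) stop("need at least one block")
  levs <- levels(block_classes[[1L]])
  n <- length(block_classes[[1L]])
  Qb <- length(block_classes)
  votes <- vapply(block_classes, as.character, character(n))
  if (n == 1L) votes <- matrix(votes, 1L, Qb)
  out <- character(n)
  for (i in seq_len(n)) {
    tally <- numeric(length(levs))
    names(tally) <- levs
    for (b in seq_len(Qb)) tally[votes[i, b]] <- tally[votes[i, b]] + weights[b]
    top <- levs[tally == max(tally)]
    if (length(top) == 1L) {
      out[i] <- top
    } else {
      voters <- which(votes[i, ] %in% top)
      best <- voters[which.max(weights[voters])]   # earliest block on weight ties
      out[i] <- votes[i, best]
    }
  }
  factor(out, levels = levs)
}

#' Classification performance report
#'
#' Overall accuracy, per-class one-vs-rest precision/recall/F1 (undefined
#' ratios reported as 0 and flagged) and the confusion matrix (true
#' classes in rows).
#'
#' @param y_true,y_pred class vectors of equal length.
#' @return List with `accuracy`, `per_class` (data frame), `confusion` and
#'   `undefined` (classes with an undefined precision or F1).
#' @export
performance_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  levs <- union(levels(as.factor(y_true)), levels(as.factor(y_pred)))
  y_true <- factor(y_true, levels = levs)
  y_pred <- factor(y_pred, levels = levs)
  confusion <- table(true = y_true, predicted = y_pred)
  accuracy <- mean(y_true == y_pred)
  undefined <- character(0L)
  per_class <- do.call(rbind, lapply(levs, function(k) {
    tp <- sum(y_true == k & y_pred == k)
    fp <- sum(y_true != k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    precision <- if (tp + fp == 0) { undefined <<- c(undefined, k); 0 } else tp / (tp + fp)
    recall <- if (tp + fn == 0) { undefined <<- c(undefined, k); 0 } else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
    data.frame(class = k, precision = precision, recall = recall, f1 = f1)
  }))
  list(accuracy = accuracy, per_class = per_class, confusion = confusion,
       undefined = unique(undefined))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U statistic divided by `n_pos * n_neg`,
#' with tied scores counting 1/2 (midrank formulation).
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels binary labels: logical, 0/1, or a factor whose second
#'   level is the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("both label values must be present")
  r <- rank(scores)   # midranks handle ties as 1/2
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Per-block, per-component one-vs-rest AUC
#'
#' For each block, component and class, the ROC score of a sample is the
#' negative one-dimensional distance of that component's score to the
#' class centroid.
#'
#' @param model fitted [sgcca()] object.
#' @param scores named list of `n x H` score matrices (e.g. from
#'   [sgcca_transform()]).
#' @param labels true classes for the scored samples.
#' @return Named list (per block) of `K x H` AUC matrices.
#' @export
component_auc <- function(model, scores, labels) {
  labels <- factor(labels, levels = model$classes)
  lapply(stats::setNames(model$block_names, model$block_names), function(q) {
    ctr <- model$centroids[[q]]
    out <- matrix(NA_real_, nrow(ctr), ncol(ctr),
                  dimnames = list(rownames(ctr), paste0("comp", seq_len(ncol(ctr)))))
    for (k in seq_len(nrow(ctr))) {
      for (h in seq_len(ncol(ctr))) {
        sc <- -abs(scores[[q]][, h] - ctr[k, h])
        out[k, h] <- roc_auc(sc, labels == rownames(ctr)[k])
      }
    }
    out
  })
}
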