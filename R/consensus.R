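# Stability / consensus feature selection over repeated stratified
# train/test partitions, and the per-modality outcome-class assignment of
# each selected feature.

#' Refit over repeated stratified partitions
#'
#' Fits one model per partition (partition p uses seed `base_seed + p` for
#' its 70/30 stratified split), predicts the held-out samples, and
#' accumulates every nonzero loading. The sparsity `keepX` is tuned once
#' beforehand and held fixed across partitions.
#'
#' @param blocks named list of samples-by-features matrices.
#' @param labels class vector.
#' @param keepX fixed per-block, per-component feature counts.
#' @param ncomp number of components.
#' @param C optional design matrix (computed once from the full data when
#'   `NULL`).
#' @param n_partitions number of repeated partitions (default 30).
#' @param train_frac training fraction per partition (default 0.7).
#' @param base_seed integer seed base.
#' @return List of class `"consensus_fit"` with `records` (long data frame
#'   of nonzero loadings: partition, block, component, feature, loading),
#'   `performance` (per-partition test accuracy and metric reports),
#'   `n_partitions`.
#' @export
consensus_fit <- function(blocks, labels, keepX, ncomp, C = NULL,
                          n_partitions = 30L, train_frac = 0.7,
                          base_seed = 1L) {
  labels <- as.factor(labels)
  if (is.null(C)) C <- build_design(blocks)
  records <- vector("list", n_partitions)
  reports <- vector("list", n_partitions)
  accuracy <- numeric(n_partitions)
  for (p in seq_len(n_partitions)) {
    sp <- stratified_split(stats::setNames(labels, rownames(blocks[[1L]])),
                           train_frac = train_frac, seed = base_seed + p)
    train <- match(sp$train, rownames(blocks[[1L]]))
    test <- match(sp$test, rownames(blocks[[1L]]))
    fp <- fit_predict_split(blocks, labels, train, test, keepX, ncomp, C)
    sel <- selected_features(fp$model)
    sel$partition <- p
    records[[p]] <- sel
    reports[[p]] <- fp$metrics
    accuracy[p] <- fp$metrics$accuracy
  }
  structure(list(records = do.call(rbind, records),
                 performance = list(accuracy = accuracy, reports = reports),
                 n_partitions = as.integer(n_partitions)),
            class = "consensus_fit")
}

#' @export
print.consensus_fit <- function(x, ...) {
  cat(sprintf("Consensus fit over %d partitions: mean test accuracy %.3f\n",
              x$n_partitions, mean(x$performance$accuracy)))
  invisible(x)
}

#' Per-feature selection frequency and median absolute loading
#'
#' Aggregates the long record table of a [consensus_fit()] by block,
#' component and feature. The median absolute loading is computed over the
#' partitions in which the feature was selected (no zero padding).
#'
#' @param records long data frame from [consensus_fit()] (`$records`).
#' @return Data frame with `block`, `component`, `feature`, `frequency`,
#'   `median_abs_loading`.
#' @export
stability_table <- function(records) {
  key <- interaction(records$block, records$component, records$feature,
                     drop = TRUE)
  agg <- lapply(split(records, key), function(d) {
    data.frame(block = d$block[1L], component = d$component[1L],
               feature = d$feature[1L], frequency = nrow(d),
               median_abs_loading = stats::median(abs(d$loading)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$block, out$component, -out$frequency,
                   -out$median_abs_loading), ]
  rownames(out) <- NULL
  out
}

#' Consensus selection by frequency / median-loading thresholds
#'
#' A feature is kept iff (frequency > `f1` and median absolute loading >
#' `m1`) or (frequency > `f2` and median absolute loading > `m2`), with
#' strict inequalities.
#'
#' @param records long record data frame from [consensus_fit()], or an
#'   already aggregated [stability_table()].
#' @param f1,m1 first clause thresholds (defaults 15 and 0.05).
#' @param f2,m2 second clause thresholds (defaults 10 and 0.2).
#' @return Data frame of selected rows of the stability table plus a
#'   `rule_clause` column (`"freq"`, `"loading"` or `"both"`).
#' @export
select_consensus <- function(records, f1 = 15, m1 = 0.05, f2 = 10, m2 = 0.2) {
  tab <- if (all(c("frequency", "median_abs_loading") %in% names(records))) {
    records
  } else {
    stability_table(records)
  }
  c1 <- tab$frequency > f1 & tab$median_abs_loading > m1
  c2 <- tab$frequency > f2 & tab$median_abs_loading > m2
  out <- tab[c1 | c2, , drop = FALSE]
  out$rule_clause <- ifelse(c1[c1 | c2] & c2[c1 | c2], "both",
                            ifelse(c1[c1 | c2], "freq", "loading"))
  rownames(out) <- NULL
  out
}

#' Outcome class of an expression feature from pairwise DE results
#'
#' A class qualifies when both of its pairwise contrasts are significant
#' (FDR < `alpha`) with a consistent direction relative to that class; its
#' score is the smaller absolute log fold change of the two. The outcome
#' is the qualifying class with the largest score. When no class
#' qualifies, the fallback is the contrast with the smallest FDR, assigning
#' the class of that pair with the higher mean expression (flagged
#' low-confidence).
#'
#' @param gene gene / feature name.
#' @param de_list named list of pairwise DE tables (data frames with
#'   `gene`, `logFC`, `fdr`), where each element has an attribute `groups`
#'   of the two class names and `logFC > 0` means up in the first.
#' @param class_means named vector of per-class mean expression for the
#'   gene (used by the fallback).
#' @param alpha significance level (default 0.05).
#' @return List with `class`, `confident` (logical) and `score`.
#' @export
assign_outcome_expression <- function(gene, de_list, class_means,
                                      alpha = 0.05) {
  pairs <- lapply(de_list, function(d) {
    g <- attr(d, "groups")
    if (is.null(g) || length(g) != 2L) stop("each DE table needs a 'groups' attribute")
    row <- d[d$gene == gene, , drop = FALSE]
    if (nrow(row) == 0L) return(NULL)
    list(groups = g, logFC = row$logFC[1L], fdr = row$fdr[1L])
  })
  pairs <- Filter(Negate(is.null), pairs)
  if (!length(pairs)) stop("gene not found in any contrast")
  classes <- unique(unlist(lapply(pairs, `[[`, "groups")))
  score <- stats::setNames(rep(NA_real_, length(classes)), classes)
  for (k in classes) {
    mine <- Filter(function(p) k %in% p$groups, pairs)
    if (length(mine) < length(classes) - 1L) next
    signs <- vapply(mine, function(p)
      if (p$groups[1L] == k) sign(p$logFC) else -sign(p$logFC), numeric(1L))
    fdrs <- vapply(mine, `[[`, numeric(1L), "fdr")
    if (all(fdrs < alpha) && length(unique(signs)) == 1L && all(signs != 0)) {
      score[k] <- min(vapply(mine, function(p) abs(p$logFC), numeric(1L)))
    }
  }
  if (any(!is.na(score))) {
    best <- names(score)[order(-score)][1L]
    return(list(class = best, confident = TRUE, score = score[[best]]))
  }
  # fallback: smallest-FDR contrast, class with the higher mean expression
  fdrs <- vapply(pairs, `[[`, numeric(1L), "fdr")
  g <- pairs[[which.min(fdrs)]]$groups
  means <- class_means[g]
  best <- if (any(is.na(means)) || means[1L] == means[2L]) g[1L] else
    g[which.max(means)]
  list(class = unname(best), confident = FALSE, score = NA_real_)
}

#' Outcome class of a methylation feature
#'
#' The class whose mean beta value differs most, on average, from the
#' other classes: `d_k = mean_{j != k} |m_k - m_j|`, ties broken by class
#' order.
#'
#' @param class_means named vector of per-class mean beta values.
#' @return List with `class` and `confident` (`FALSE` on an exact tie).
#' @export
assign_outcome_methylation <- function(class_means) {
  K <- length(class_means)
  if (K < 2L) stop("need at least 2 class means")
  d <- vapply(seq_len(K), function(k)
    mean(abs(class_means[k] - class_means[-k])), numeric(1L))
  best <- which.max(d)   # first maximum on ties
  list(class = names(class_means)[best] %||% best,
       confident = sum(d == max(d)) == 1L)
}

#' Outcome class of a miRNA feature (two classes)
#'
#' The class with the higher mean expression.
#'
#' @param class_means named vector of exactly two class means.
#' @return List with `class` and `confident` (`FALSE` on an exact tie).
#' @export
assign_outcome_mirna <- function(class_means) {
  if (length(class_means) != 2L) stop("miRNA outcome assignment needs exactly 2 classes")
  best <- which.max(class_means)   # first on ties
  list(class = names(class_means)[best] %||% best,
       confident = class_means[1L] != class_means[2L])
}
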