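# Count-based differential expression between two classes: low-count
# filtering, TMM normalization, a negative-binomial likelihood-ratio test
# with moment-based shrunken dispersions, BH adjustment, the sloped
# relevance cut-line, and the signed -log10 p rank metric for GSEA input.

#' Filter genes with very low counts
#'
#' Keeps genes with counts-per-million strictly above `min_cpm` in at
#' least `min_samples` samples (default: the smallest group size).
#'
#' @param counts genes-by-samples nonnegative integer matrix.
#' @param groups two-level class vector (used for the default
#'   `min_samples`).
#' @param min_cpm CPM threshold (strict `>`).
#' @param min_samples minimum number of samples above threshold.
#' @return Character vector of kept gene names.
#' @export
filter_low_counts <- function(counts, groups = NULL, min_cpm = 1,
                              min_samples = NULL) {
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(min_samples)) {
    if (is.null(groups)) stop("need 'groups' or an explicit 'min_samples'")
    min_samples <- min(table(groups))
  }
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  cpm <- sweep(counts, 2L, colSums(counts), "/") * 1e6
  keep <- rowSums(cpm > min_cpm) >= min_samples
  if (!any(keep)) stop("no genes left after low-count filtering")
  rownames(counts)[keep]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values library-composition factors (computed with
#' edgeR): the reference sample is the one whose upper-quartile CPM is
#' closest to the mean, M and A values are doubly trimmed (30% on M, 5% on
#' A), and the factors are rescaled to a unit geometric mean.
#'
#' @param counts genes-by-samples count matrix (at least 2 samples).
#' @param trim_M,trim_A trim fractions for the M and A values.
#' @return Named per-sample normalization factors.
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  f <- edgeR::calcNormFactors(counts, method = "TMM", logratioTrim = trim_M,
                              sumTrim = trim_A)
  stats::setNames(as.numeric(f), colnames(counts))
}

# Moment estimate of the NB dispersion for one gene given fitted means.
# E[(y - mu)^2] = mu + phi mu^2  =>  phi = (RSS - sum(mu)) / sum(mu^2),
# with the residual sum of squares rescaled by n / (n - n_par) to undo the
# degrees of freedom absorbed by the fitted group means.
moment_dispersion <- function(y, mu, n_par = 2L) {
  denom <- sum(mu^2)
  if (denom == 0) return(0)
  n <- length(y)
  rss <- sum((y - mu)^2) * n / max(n - n_par, 1L)
  max(0, (rss - sum(mu)) / denom)
}

#' Negative-binomial quasi-likelihood F-test between two groups
#'
#' Per gene, a negative-binomial GLM with log link and offsets
#' `log(library size x TMM factor)` is fit with and without the group
#' effect. The deviance drop, divided by the full model's residual
#' deviance per degree of freedom, is referred to an F distribution with
#' `(1, n - 2)` df -- the quasi-likelihood form, which keeps the test
#' calibrated at small group sizes. The dispersion is a per-gene moment
#' estimate (residual-df corrected) shrunk toward the trimmed-mean common
#' dispersion (`shrink_weight` on the gene, the rest on the common value).
#' Log fold changes (base 2, first group over second) come from group mean
#' CPM with a prior count.
#'
#' @param counts genes-by-samples count matrix.
#' @param groups two-level factor; `logFC > 0` means higher in the first
#'   level.
#' @param factors optional TMM factors (computed via [tmm_factors()] when
#'   `NULL`).
#' @param shrink_weight weight of the per-gene dispersion estimate
#'   (default 0.25; the complement goes to the common dispersion).
#' @param prior_count prior count for the CPM fold-change (default 0.5).
#' @param dispersion_trim trim fraction for the common-dispersion mean.
#' @return Data frame with `gene`, `logFC`, `p`, `dispersion`.
#' @export
nb_de_test <- function(counts, groups, factors = NULL, shrink_weight = 0.25,
                       prior_count = 0.5, dispersion_trim = 0.25) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly 2 groups are required")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 samples")
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be nonnegative integers")
  }
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(factors)) factors <- tmm_factors(counts)
  lib <- colSums(counts) * factors
  offset <- log(lib)
  g1 <- groups == levels(groups)[1L]

  # group-mean fitted values for the moment dispersion estimates
  m <- exp(offset)
  lam <- cbind(rowSums(counts[, g1, drop = FALSE]) / sum(m[g1]),
               rowSums(counts[, !g1, drop = FALSE]) / sum(m[!g1]))
  mu_hat <- sweep(lam[, ifelse(g1, 1L, 2L), drop = FALSE], 2L, m, "*")
  phi_gene <- vapply(seq_len(nrow(counts)), function(i)
    moment_dispersion(counts[i, ], mu_hat[i, ]), numeric(1L))
  phi_common <- mean(phi_gene, trim = dispersion_trim)
  phi <- pmax(shrink_weight * phi_gene + (1 - shrink_weight) * phi_common, 1e-4)

  x_alt <- stats::model.matrix(~groups)
  x_null <- x_alt[, 1L, drop = FALSE]
  n_s <- ncol(counts)
  p <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    fam <- MASS::negative.binomial(theta = 1 / phi[i])
    y <- counts[i, ]
    f_alt <- suppressWarnings(stats::glm.fit(x_alt, y, family = fam, offset = offset))
    f_null <- suppressWarnings(stats::glm.fit(x_null, y, family = fam, offset = offset))
    s2 <- f_alt$deviance / (n_s - 2L)
    fstat <- max(0, f_null$deviance - f_alt$deviance) / max(s2, 1e-8)
    p[i] <- stats::pf(fstat, 1L, n_s - 2L, lower.tail = FALSE)
  }
  cpm1 <- 1e6 * (rowSums(counts[, g1, drop = FALSE]) + prior_count) / sum(lib[g1])
  cpm2 <- 1e6 * (rowSums(counts[, !g1, drop = FALSE]) + prior_count) / sum(lib[!g1])
  data.frame(gene = rownames(counts), logFC = log2(cpm1 / cpm2), p = p,
             dispersion = phi, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p vector of p-values in `[0, 1]` (no NAs).
#' @return FDR-adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p))) stop("NA/NaN p-values")
  if (any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Relevance classification on the sloped significance/fold-change cut-line
#'
#' Among genes with FDR < 0.05, a gene is positively relevant when
#' `-log10(FDR) > M + logFC * (c - M)` and negatively relevant when
#' `-log10(FDR) > M + logFC * (log10(0.05) + M)`, where
#' `M = max(-log10(FDR))` over the contrast and `c = -log10(0.05)`. The
#' boundary passes through `-log10(0.05)` at `logFC = +/-1` and through
#' `M` at `logFC = 0`. Remaining significant genes are
#' `"significant_not_relevant"`, the rest `"ns"`. When `M <= c` the line is
#' degenerate; the classification falls back to FDR < 0.05 and
#' `|logFC| > 1` (flagged via a warning).
#'
#' @param logFC log2 fold changes.
#' @param fdr BH-adjusted p-values (the full contrast; `M` is their
#'   maximum `-log10`).
#' @param alpha significance level (default 0.05).
#' @return Factor with levels `pos_relevant`, `neg_relevant`,
#'   `significant_not_relevant`, `ns`; attribute `M` carries the cut-line
#'   summit.
#' @export
relevance_cutline <- function(logFC, fdr, alpha = 0.05) {
  if (length(logFC) != length(fdr)) stop("length mismatch")
  nl <- -log10(pmax(fdr, .Machine$double.xmin))
  M <- max(nl)
  cc <- -log10(alpha)
  sig <- fdr < alpha
  status <- rep("ns", length(logFC))
  if (M <= cc) {
    warning("degenerate cut-line (max -log10(FDR) <= -log10(alpha)); ",
            "falling back to |logFC| > 1")
    status[sig & logFC > 1] <- "pos_relevant"
    status[sig & logFC < -1] <- "neg_relevant"
    status[sig & abs(logFC) <= 1] <- "significant_not_relevant"
  } else {
    thr_pos <- M + logFC * (cc - M)
    thr_neg <- M + logFC * (log10(alpha) + M)
    status[sig] <- "significant_not_relevant"
    status[sig & nl > thr_pos] <- "pos_relevant"
    status[sig & nl > thr_neg] <- "neg_relevant"
  }
  structure(factor(status, levels = c("pos_relevant", "neg_relevant",
                                      "significant_not_relevant", "ns")),
            M = M)
}

#' Signed significance rank metric
#'
#' `-log10(p) * sign(logFC)`, the per-gene statistic used to pre-rank
#' genes for gene-set enrichment analysis. `p = 0` is clamped to the
#' smallest positive double (with a warning).
#'
#' @param p p-values in `(0, 1]`.
#' @param logFC log fold changes (sign only is used).
#' @return Numeric scores.
#' @export
rank_metric <- function(p, logFC) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  if (any(p == 0, na.rm = TRUE)) {
    warning("p = 0 clamped to the smallest positive double")
    p <- pmax(p, .Machine$double.xmin)
  }
  -log10(p) * sign(logFC)
}

#' Full two-group differential-expression contrast
#'
#' Filter, TMM-normalize, test, adjust and classify: the complete path
#' for one pairwise contrast. The returned table carries a `groups`
#' attribute naming the two classes (first = logFC numerator), as consumed
#' by [assign_outcome_expression()].
#'
#' @inheritParams nb_de_test
#' @param min_cpm,min_samples low-count filter settings (see
#'   [filter_low_counts()]).
#' @param alpha FDR significance level.
#' @return Data frame with `gene`, `logFC`, `p`, `fdr`, `status`,
#'   `rank_metric`.
#' @export
de_contrast <- function(counts, groups, min_cpm = 1, min_samples = NULL,
                        alpha = 0.05, ...) {
  groups <- droplevels(as.factor(groups))
  keep <- filter_low_counts(counts, groups, min_cpm = min_cpm,
                            min_samples = min_samples)
  counts <- counts[keep, , drop = FALSE]
  res <- nb_de_test(counts, groups, ...)
  res$fdr <- bh_adjust(res$p)
  res$status <- relevance_cutline(res$logFC, res$fdr, alpha = alpha)
  res$rank_metric <- rank_metric(res$p, res$logFC)
  attr(res, "groups") <- levels(groups)
  res
}

#' Write a pre-ranked gene list (.rnk)
#'
#' Two-column tab-separated file (gene, rank metric), sorted decreasing.
#'
#' @param de data frame from [de_contrast()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_rnk <- function(de, path) {
  ord <- order(-de$rank_metric)
  utils::write.table(de[ord, c("gene", "rank_metric")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
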