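# Feature filtering, sample intersection, stratified splitting and
# train-statistics standardization.

#' Near-zero-variance feature filter
#'
#' Removes features with zero variance, or with very few unique values
#' relative to the number of samples (fraction of distinct values below
#' `unique_cutoff`) together with a large ratio of the most common to the
#' second most common value frequency (above `freq_ratio_cutoff`; the
#' default 19 encodes a 95/5 ratio).
#'
#' @param x samples-by-features numeric matrix with column names.
#' @param unique_cutoff distinct-value fraction below which a feature is a
#'   near-zero-variance candidate.
#' @param freq_ratio_cutoff frequency-ratio threshold (strict `>`).
#' @return Character vector of kept feature names, in input order.
#' @export
nzv_filter <- function(x, unique_cutoff = 0.10, freq_ratio_cutoff = 19.0) {
  if (is.null(dim(x)) || nrow(x) < 2L || ncol(x) == 0L) {
    stop("'x' must be a matrix with at least 2 samples and 1 feature")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  n <- nrow(x)
  keep <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) == 1L) return(FALSE)              # zero variance
    ratio <- as.numeric(tab[1L]) / as.numeric(tab[2L])
    distinct_frac <- length(tab) / n
    !(distinct_frac < unique_cutoff && ratio > freq_ratio_cutoff)
  }, logical(1L))
  colnames(x)[keep]
}

#' Restrict blocks and sample table to their common samples
#'
#' @param blocks named list of samples-by-features matrices with sample IDs
#'   as row names.
#' @param sample_table data frame with a `sample_id` column and optionally
#'   `class`, `time`, `event`.
#' @return List with `blocks` (all restricted to the intersection, in the
#'   first block's sample order) and `samples` (matching rows of
#'   `sample_table`).
#' @export
intersect_samples <- function(blocks, sample_table = NULL) {
  ids <- lapply(blocks, rownames)
  if (any(vapply(ids, is.null, logical(1L)))) {
    stop("every block needs sample IDs as row names")
  }
  common <- Reduce(intersect, ids)
  if (!is.null(sample_table)) common <- intersect(common, sample_table$sample_id)
  if (length(common) == 0L) stop("no samples shared by all inputs")
  if (length(common) == 1L) warning("only one sample shared by all inputs")
  common <- ids[[1L]][ids[[1L]] %in% common]
  out <- lapply(blocks, function(b) b[common, , drop = FALSE])
  samples <- if (is.null(sample_table)) NULL else
    sample_table[match(common, sample_table$sample_id), , drop = FALSE]
  list(blocks = out, samples = samples)
}

#' Stratified train/test split
#'
#' Per-class training counts are `round(train_frac * class size)` (half
#' away from zero), with any shortfall or overflow relative to the global
#' target corrected on the largest class, so class proportions are
#' preserved within rounding.
#'
#' @param labels class vector (factor or character), optionally named by
#'   sample ID.
#' @param train_frac training fraction in (0, 1).
#' @param seed integer seed for the shuffling.
#' @return List with `train` and `test` (names of `labels` if named, else
#'   integer indices), and `seed`.
#' @export
stratified_split <- function(labels, train_frac = 0.7, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts < 2L)) stop("every class needs at least 2 samples")
  n_train_k <- floor(train_frac * as.numeric(counts) + 0.5)
  n_train_k <- pmin(pmax(n_train_k, 1L), as.numeric(counts) - 1L)
  target <- floor(train_frac * length(labels) + 0.5)
  big <- which.max(counts)
  n_train_k[big] <- min(max(n_train_k[big] + (target - sum(n_train_k)), 1L),
                        counts[big] - 1L)
  idx <- seq_along(labels)
  train <- integer(0L)
  with_seed(seed, {
    for (k in seq_along(counts)) {
      cls <- idx[labels == levels(labels)[k]]
      train <- c(train, sample(cls, n_train_k[k]))
    }
  })
  train <- sort(train)
  test <- setdiff(idx, train)
  if (!is.null(names(labels))) {
    train <- names(labels)[train]
    test <- names(labels)[test]
  }
  list(train = train, test = test, seed = as.integer(seed))
}

#' Standardize a training matrix and keep the statistics
#'
#' Columns are centered and scaled to unit standard deviation (denominator
#' `n - 1`); the training statistics are returned so that test data can be
#' transformed identically via [apply_scaling()].
#'
#' @param x samples-by-features numeric training matrix.
#' @return List with `x` (standardized matrix) and `params` (list with
#'   `center` and `scale` vectors).
#' @export
center_scale <- function(x) {
  ctr <- colMeans(x)
  scl <- col_sds(x)
  if (any(scl <= 0 | !is.finite(scl))) {
    stop("zero-standard-deviation feature; filter before scaling")
  }
  params <- list(center = ctr, scale = scl)
  list(x = apply_scaling(x, params), params = params)
}

#' Apply stored standardization parameters
#'
#' @param x samples-by-features matrix (same features as the training data).
#' @param params `params` element of a [center_scale()] result.
#' @return Standardized matrix.
#' @export
apply_scaling <- function(x, params) {
  if (ncol(x) != length(params$center)) stop("feature mismatch with scaling parameters")
  sweep(sweep(x, 2L, params$center, "-"), 2L, params$scale, "/")
}

#' Read an omics block from TSV/CSV
#'
#' @param path file path; tab- or comma-delimited, with a header row of
#'   sample IDs and the first column holding feature names (the layout
#'   written by [write_dataset()]).
#' @param features_in_rows if `TRUE` (default) the file stores features in
#'   rows; the returned matrix is always samples-by-features.
#' @param sep field separator (default tab).
#' @return Numeric samples-by-features matrix.
#' @export
read_block <- function(path, features_in_rows = TRUE, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (features_in_rows) m <- t(m)
  storage.mode(m) <- "double"
  m
}

#' Read a sample table (sample_id, class, time, event)
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_samples <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read a feature blacklist (one feature name per line)
#'
#' Used to drop, e.g., methylation probes excluded by array-annotation
#' rules that require an external manifest.
#'
#' @param path text file path.
#' @return Character vector of feature names.
#' @export
read_blacklist <- function(path) {
  out <- readLines(path, warn = FALSE)
  out[nzchar(trimws(out))]
}
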