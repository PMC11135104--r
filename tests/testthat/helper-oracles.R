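# Independent oracles and instance generators shared across tests.

# Brute-force Benjamini-Hochberg step-up, written directly from the
# procedure: sort, p_i * n / i, cumulative min from the largest rank.
bh_bruteforce <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- (n / seq_len(n)) * p[ord]
  if (n > 1L) {
    for (i in seq(n - 1L, 1L)) adj[i] <- min(adj[i], adj[i + 1L])
  }
  out <- numeric(n)
  out[ord] <- pmin(adj, 1)
  out
}

# All-pairs concordance AUC (ties count 1/2).
auc_bruteforce <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (a in pos) for (b in neg) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# Direct double-loop evaluation of the design-weighted covariance sum.
objective_direct <- function(blocks, loadings, C) {
  B <- length(blocks)
  val <- 0
  for (q in seq_len(B)) {
    for (j in seq_len(B)) {
      if (q < j) {
        tq <- drop(blocks[[q]] %*% loadings[[q]])
        tj <- drop(blocks[[j]] %*% loadings[[j]])
        val <- val + C[q, j] * sum((tq - mean(tq)) * (tj - mean(tj))) /
          (length(tq) - 1)
      }
    }
  }
  val
}

# A standardized one-block + outcome instance whose class signal lives in
# one shared latent direction with equal-magnitude loadings on the first
# `k` features ("signal-dominant": the sparse solution is unambiguous).
signal_instance <- function(n = 60, p = 12, k = 3, noise = 0.05, classes = 3) {
  labs <- factor(sample(rep(paste0("c", seq_len(classes)), length.out = n)))
  dm <- dummy_matrix(labs)
  w <- rnorm(classes)
  w <- w - mean(w)                     # the constant direction is null
  w <- w / sqrt(sum(w^2))
  u <- drop(dm$y_centered %*% w)
  X <- matrix(rnorm(n * p), n) * noise
  sgn <- sample(c(-1, 1), k, replace = TRUE)
  for (j in seq_len(k)) X[, j] <- X[, j] + sgn[j] * u
  list(X = scale(X), yc = dm$y_centered, labels = labs,
       C = matrix(c(0, 1, 1, 0), 2))
}

# Small three-class multi-omics dataset for fast end-to-end tests.
small_study <- function(seed = 11, n = c(30, 30, 30), p = 80, k = 15,
                        separation = 3) {
  generate_study(sim_config(
    n_per_class = n,
    block_specs = list(block_spec("mrna", p, k, "gaussian"),
                       block_spec("meth", p, k, "beta")),
    class_separation = separation, seed = seed))
}
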