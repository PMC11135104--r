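test_that("low-count filtering keeps genes by CPM in enough samples", {
  counts <- rbind(zero = c(0, 0, 0, 0),
                  high = c(500, 400, 300, 600),
                  rare = c(5, 0, 0, 0))
  colnames(counts) <- paste0("s", 1:4)
  groups <- factor(c("a", "a", "b", "b"))
  keep <- filter_low_counts(counts, groups)
  expect_true("high" %in% keep)
  expect_false("zero" %in% keep)
  expect_false("rare" %in% keep)
  # a gene exactly at the threshold is removed (strict >)
  counts2 <- rbind(at = c(1, 1), anchor = c(999999, 999999))
  expect_equal(filter_low_counts(counts2, min_cpm = 1, min_samples = 2), "anchor")
  expect_error(filter_low_counts(counts2, min_cpm = Inf, min_samples = 1),
               "no genes")
  expect_error(filter_low_counts(counts["zero", , drop = FALSE], groups),
               "all-zero")
})

test_that("TMM factors are neutral for proportional libraries", {
  set.seed(1)
  base <- matrix(rnbinom(2000, mu = 100, size = 10), 500, 4)
  rownames(base) <- paste0("g", 1:500)
  colnames(base) <- paste0("s", 1:4)
  expect_equal(unname(tmm_factors(cbind(base, base)[, c(1, 5)])), c(1, 1))
  doubled <- cbind(s1 = base[, 1], s2 = base[, 1] * 2L)
  expect_equal(unname(tmm_factors(doubled)), c(1, 1), tolerance = 1e-12)
  f <- tmm_factors(base)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  # invariant to a global rescaling of every library
  expect_equal(tmm_factors(base * 3L), f, tolerance = 1e-12)
  expect_error(tmm_factors(base[, 1, drop = FALSE]), "2 samples")
})

test_that("the NB test is unbiased under the null and finds real shifts", {
  set.seed(2)
  G <- 800; n <- 20
  mu <- exp(runif(G, log(20), log(500)))
  counts <- matrix(rnbinom(G * n, mu = rep(mu, n), size = 10), G, n,
                   dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
  groups <- factor(rep(c("A", "B"), each = 10))
  res <- nb_de_test(counts, groups)
  # identical group distributions give near-zero logFC on average
  expect_lt(abs(mean(res$logFC)), 0.05)
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.03)
  # a 4-fold shift is detected with high power at FDR 0.05
  shifted <- counts
  idx <- 1:100
  shifted[idx, groups == "A"] <-
    matrix(rnbinom(100 * 10, mu = rep(mu[idx] * 4, 10), size = 10), 100, 10)
  res2 <- nb_de_test(shifted, groups)
  fdr <- bh_adjust(res2$p)
  expect_gt(mean(fdr[idx] < 0.05), 0.8)
  expect_true(all(res2$logFC[idx][fdr[idx] < 0.05] > 0))
  expect_error(nb_de_test(counts + 0.5, groups), "integers")
  expect_error(nb_de_test(counts, factor(rep("A", n))), "2 groups")
})

test_that("BH adjustment equals the brute-force step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.05)), c(0.03, 0.03, 0.05))
  expect_equal(bh_adjust(0.42), 0.42)
  set.seed(3)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, bh_bruteforce(p), tolerance = 1e-15)
    expect_true(all(adj >= p))
  }
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  expect_error(bh_adjust(c(0.1, 2)), "in \\[0, 1\\]")
})

test_that("the relevance cut-line reproduces its plug-in identities", {
  # vectors engineered so max(-log10 FDR) = 10
  anchor_fdr <- 1e-10
  s <- function(fdr, lfc) {
    relevance_cutline(c(3, lfc), c(anchor_fdr, fdr))[2]
  }
  expect_equal(as.character(s(0.04, 1.0)), "pos_relevant")
  expect_equal(as.character(s(1e-6, 0.2)), "significant_not_relevant")
  expect_equal(as.character(s(0.04, -1.0)), "neg_relevant")
  # boundary identities: at logFC = +/-1 the threshold is -log10(0.05)
  M <- 10; cc <- -log10(0.05)
  expect_equal(M + 1 * (cc - M), cc)
  expect_equal(M + (-1) * (log10(0.05) + M), cc)
  status <- relevance_cutline(c(3, 0), c(anchor_fdr, 0.04))
  expect_equal(attr(status, "M"), 10)
  expect_equal(as.character(status[2]), "significant_not_relevant")
  # non-significant genes stay out regardless of fold change
  expect_equal(as.character(relevance_cutline(c(3, 8), c(anchor_fdr, 0.2))[2]),
               "ns")
  # a degenerate summit (no FDR below alpha) is flagged; nothing is relevant
  expect_warning(
    st <- relevance_cutline(c(2, 0.5), c(0.06, 0.3)), "degenerate")
  expect_equal(as.character(st), c("ns", "ns"))
})

test_that("the rank metric is a signed log significance", {
  expect_equal(rank_metric(0.01, -2), -2)
  expect_equal(rank_metric(1, 3), 0)
  expect_equal(rank_metric(0.5, 0), 0)
  expect_warning(r0 <- rank_metric(0, 1), "clamped")
  expect_true(is.finite(r0) && r0 > 300)
})

test_that("a full contrast returns a coherent table", {
  lat <- generate_latent(c(10, 10), separation = 2, seed = 4)
  cnt <- generate_block(lat$latent, block_spec("c", 400, 40, "counts",
                                               loading_scale = 0.8), seed = 5)
  counts <- t(cnt$x)
  res <- de_contrast(counts, lat$labels)
  expect_true(all(c("gene", "logFC", "p", "fdr", "status", "rank_metric") %in%
                    names(res)))
  expect_equal(attr(res, "groups"), levels(lat$labels))
  expect_true(all(res$fdr >= res$p))
  path <- withr::local_tempfile(fileext = ".rnk")
  write_rnk(res, path)
  rnk <- read.table(path, sep = "\t")
  expect_equal(nrow(rnk), nrow(res))
  expect_true(!is.unsorted(rev(rnk$V2)))
})
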