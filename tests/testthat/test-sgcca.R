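test_that("dummy matrix encodes classes in first-appearance order", {
  dm <- dummy_matrix(c("B", "A", "B"))
  expect_equal(dm$classes, c("B", "A"))
  expect_equal(unname(colSums(dm$y)), c(2, 1))
  expect_equal(unname(colMeans(dm$y_centered)), c(0, 0))
  expect_true(all(rowSums(dm$y) == 1))
  expect_error(dummy_matrix(c("A", "A")), "2 classes")
})

test_that("soft-thresholding to cardinality matches hand computations", {
  z <- c(3, 1, -2)
  expect_equal(soft_threshold_k(z, 3), z / sqrt(sum(z^2)))
  expect_equal(soft_threshold_k(z, 1), c(1, 0, 0))
  expect_equal(soft_threshold_k(z, 2), c(2, 0, -1) / sqrt(5))
  # k nonzeros in the absence of ties; unit norm
  set.seed(1)
  for (i in 1:20) {
    zz <- rnorm(30)
    k <- sample(29, 1)
    out <- soft_threshold_k(zz, k)
    expect_equal(sum(out != 0), k)
    expect_equal(sum(out^2), 1)
  }
  # degenerate all-zero input is flagged
  out0 <- soft_threshold_k(numeric(4), 2)
  expect_true(all(out0 == 0))
  expect_true(attr(out0, "degenerate"))
  expect_error(soft_threshold_k(z, 0), "k must be")
})

test_that("objective matches a direct double-loop evaluation", {
  set.seed(2)
  n <- 25
  blocks <- list(scale(matrix(rnorm(n * 6), n)), scale(matrix(rnorm(n * 4), n)),
                 scale(matrix(rnorm(n * 3), n)))
  loadings <- lapply(blocks, function(b) {
    v <- rnorm(ncol(b))
    v / sqrt(sum(v^2))
  })
  C <- matrix(c(0, 0.4, 1, 0.4, 0, 0.7, 1, 0.7, 0), 3)
  expect_equal(sgcca_objective(blocks, loadings, C),
               objective_direct(blocks, loadings, C), tolerance = 1e-12)
  zero <- lapply(blocks, function(b) numeric(ncol(b)))
  expect_equal(sgcca_objective(blocks, zero, C), 0)
  # identical blocks, identical loadings, c = 1: objective is a variance
  ident <- sgcca_objective(blocks[c(1, 1)], loadings[c(1, 1)],
                           matrix(c(0, 1, 1, 0), 2))
  expect_gte(ident, 0)
  expect_equal(ident, var(drop(blocks[[1]] %*% loadings[[1]])))
})

test_that("deflation removes the score direction and is idempotent", {
  set.seed(3)
  x <- matrix(rnorm(60), 20, 3)
  t <- rnorm(20)
  x[, 2] <- t
  d <- deflate(x, t)
  expect_lt(max(abs(crossprod(t, d$x))), 1e-10)
  expect_lt(max(abs(d$x[, 2])), 1e-12)
  expect_equal(deflate(d$x, t)$x, d$x, tolerance = 1e-12)
  expect_error(deflate(x, numeric(20)), "zero score")
})

test_that("unpenalized single-block fit recovers the SVD direction", {
  set.seed(4)
  for (i in 1:10) {
    n <- 40; p <- 15
    X <- scale(matrix(rnorm(n * p), n))
    labs <- factor(sample(rep(c("a", "b", "c"), length.out = n)))
    dm <- dummy_matrix(labs)
    fc <- sgccaDA:::fit_component(list(X), dm$y_centered,
                                  matrix(c(0, 1, 1, 0), 2), keepX = p)
    sv <- svd(crossprod(X, dm$y_centered))$u[, 1]
    expect_gt(abs(sum(fc$loadings[[1]] * sv)), 0.999)
  }
})

test_that("block updates are monotone and exactly solve the penalized subproblem", {
  set.seed(5)
  for (i in 1:25) {
    n <- 30
    X1 <- scale(matrix(rnorm(n * 12), n))
    X2 <- scale(matrix(rnorm(n * 9), n))
    labs <- factor(sample(rep(c("a", "b", "c"), each = 10)))
    dm <- dummy_matrix(labs)
    C <- matrix(c(0, 0.5, 1, 0.5, 0, 1, 1, 1, 0), 3)
    fc <- sgccaDA:::fit_component(list(X1, X2), dm$y_centered, C, c(4, 3))
    if (length(fc$objective) > 1) {
      expect_gte(min(diff(fc$objective)), -1e-9)
    }
    for (L in fc$loadings) expect_equal(sum(L^2), 1, tolerance = 1e-10)
  }
  # the soft-threshold step maximizes a'z - tau * ||a||_1 over the unit ball
  set.seed(6)
  for (i in 1:20) {
    z <- rnorm(10)
    k <- sample(8, 1)
    tau <- sort(abs(z), decreasing = TRUE)[k + 1]
    a_hat <- soft_threshold_k(z, k)
    value <- sum(a_hat * z) - tau * sum(abs(a_hat))
    for (j in 1:50) {
      cand <- rnorm(10) * rbinom(10, 1, 0.5)
      if (all(cand == 0)) next
      cand <- cand / sqrt(sum(cand^2))
      expect_lte(sum(cand * z) - tau * sum(abs(cand)), value + 1e-10)
    }
  }
})

test_that("noise-free two-block fit recovers the true supports", {
  lat <- generate_latent(c(20, 20), separation = 5, seed = 7)
  b1 <- generate_block(lat$latent, block_spec("x", 30, 4, "gaussian", noise_sd = 0),
                       seed = 8)
  b2 <- generate_block(lat$latent, block_spec("y", 25, 3, "gaussian", noise_sd = 0),
                       seed = 9)
  dm <- dummy_matrix(lat$labels)
  C <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)
  # noise-free columns outside the support are constant zero; perturb
  # infinitesimally so standardization is defined, then fit
  set.seed(10)
  X1 <- scale(b1$x + matrix(rnorm(prod(dim(b1$x))), nrow(b1$x)) * 1e-6)
  X2 <- scale(b2$x + matrix(rnorm(prod(dim(b2$x))), nrow(b2$x)) * 1e-6)
  fc <- sgccaDA:::fit_component(list(X1, X2), dm$y_centered, C, c(4, 3))
  expect_setequal(which(fc$loadings[[1]] != 0), b1$informative)
  expect_setequal(which(fc$loadings[[2]] != 0), b2$informative)
})

test_that("design separability: unlinked blocks fit independently", {
  # with two classes the centered dummy block is rank one, so its score
  # direction is fixed and a zero data-data design decouples the blocks
  set.seed(11)
  n <- 30
  X1 <- scale(matrix(rnorm(n * 8), n))
  X2 <- scale(matrix(rnorm(n * 8), n))
  labs <- factor(rep(c("a", "b"), each = 15))
  dm <- dummy_matrix(labs)
  C0 <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3)   # no data-data link
  fc_joint <- sgccaDA:::fit_component(list(X1, X2), dm$y_centered, C0, c(3, 3))
  fc_solo <- sgccaDA:::fit_component(list(X1), dm$y_centered,
                                     matrix(c(0, 1, 1, 0), 2), keepX = 3)
  expect_equal(fc_joint$loadings[[1]], fc_solo$loadings[[1]], tolerance = 1e-4)
})

test_that("fitted models satisfy their structural invariants", {
  ds <- small_study(seed = 12)
  m <- sgcca(ds$blocks, ds$labels, keepX = 10)
  expect_s3_class(m, "sgcca")
  expect_equal(m$ncomp, 2L)
  for (q in m$block_names) {
    L <- m$loadings[[q]]
    expect_true(all(colSums(L != 0) <= 10))
    expect_equal(unname(colSums(L^2)), rep(1, 2), tolerance = 1e-10)
    # deflation makes successive scores orthogonal within a block
    expect_lt(abs(sum(m$scores[[q]][, 1] * m$scores[[q]][, 2])), 1e-8)
  }
  # H = 1 equals the single-component path
  m1 <- sgcca(ds$blocks, ds$labels, keepX = 10, ncomp = 1)
  expect_equal(m1$loadings$mrna[, 1], m$loadings$mrna[, 1])
  # determinism
  expect_equal(coef(sgcca(ds$blocks, ds$labels, keepX = 10)), coef(m))
})

test_that("transform reproduces training scores and handles edge samples", {
  ds <- small_study(seed = 13)
  m <- sgcca(ds$blocks, ds$labels, keepX = 10)
  tr <- sgcca_transform(m, ds$blocks)
  for (q in m$block_names) {
    expect_equal(unname(tr[[q]]), unname(m$scores[[q]]), tolerance = 1e-10)
  }
  # a single test sample equal to a training sample gets identical scores
  one <- lapply(ds$blocks, function(b) b[3, , drop = FALSE])
  t1 <- sgcca_transform(m, one)
  expect_equal(unname(t1$mrna[1, ]), unname(m$scores$mrna[3, ]), tolerance = 1e-10)
  # an all-zero (post-scaling) sample projects to zero
  center_sample <- lapply(ds$blocks, function(b) {
    matrix(colMeans(b), 1, ncol(b), dimnames = list("z", colnames(b)))
  })
  t0 <- sgcca_transform(m, center_sample)
  expect_equal(unname(t0$mrna[1, ]), c(0, 0), tolerance = 1e-10)
  expect_error(sgcca_transform(m, one["mrna"]), "missing block")
})

test_that("strong-signal fits select features within the truth set", {
  # 20 informative features split over the two latent axes: each of the
  # two components carries 10, so keepX = 10 per component covers truth
  ds <- generate_study(sim_config(class_separation = 10, seed = 14))
  m <- sgcca(ds$blocks, ds$labels, keepX = 10)
  for (q in m$block_names) {
    sel <- rownames(m$loadings[[q]])[rowSums(m$loadings[[q]] != 0) > 0]
    jac <- length(intersect(sel, ds$truth[[q]])) /
      length(union(sel, ds$truth[[q]]))
    expect_gte(jac, 0.8)
  }
})

test_that("models survive a JSON round trip", {
  ds <- small_study(seed = 15, p = 30, k = 8)
  m <- sgcca(ds$blocks, ds$labels, keepX = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_sgcca(m, path)
  m2 <- read_sgcca(path)
  expect_equal(m2$loadings$mrna, m$loadings$mrna, tolerance = 1e-12)
  newd <- lapply(ds$blocks, function(b) b[1:5, , drop = FALSE])
  expect_equal(predict(m2, newd)$class, predict(m, newd)$class)
})

test_that("fit agrees with an independent DIABLO implementation on support recovery", {
  skip_if_not_installed("mixOmics")
  # two classes: a single latent axis, so one component carries all signal
  ds <- generate_study(sim_config(
    n_per_class = c(25, 25),
    block_specs = list(block_spec("a", 60, 8, "gaussian", noise_sd = 0.3),
                       block_spec("b", 60, 8, "gaussian", noise_sd = 0.3)),
    class_separation = 6, seed = 16))
  m <- sgcca(ds$blocks, ds$labels, keepX = 8, ncomp = 1)
  ref <- mixOmics::block.splsda(ds$blocks, ds$labels, ncomp = 1,
                                keepX = list(a = 8, b = 8))
  for (q in names(ds$blocks)) {
    ours <- rownames(m$loadings[[q]])[m$loadings[[q]][, 1] != 0]
    theirs <- rownames(ref$loadings[[q]])[ref$loadings[[q]][, 1] != 0]
    ovl <- length(intersect(ours, theirs)) / 8
    expect_gte(ovl, 0.75)
  }
})
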