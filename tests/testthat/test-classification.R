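test_that("centroids are class means with the expected equivariances", {
  set.seed(1)
  s <- matrix(rnorm(12), 6, 2)
  labs <- factor(c("a", "a", "b", "b", "c", "c"))
  ctr <- class_centroids(s, labs)
  expect_equal(ctr["a", ], colMeans(s[1:2, ]))
  # one sample per class: centroid equals that sample
  ctr1 <- class_centroids(s[c(1, 3, 5), ], factor(c("a", "b", "c")))
  expect_equal(unname(ctr1), unname(s[c(1, 3, 5), ]))
  # duplicating samples leaves centroids unchanged
  ctr2 <- class_centroids(rbind(s, s), factor(rep(labs, 2)))
  expect_equal(ctr2, ctr)
  expect_error(class_centroids(s, factor(c("a", "a", "a", "a", "a", "b"),
                                         levels = c("a", "b", "c"))), "empty class")
})

test_that("centroid prediction matches a brute-force distance loop", {
  set.seed(2)
  ctr <- matrix(rnorm(6), 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  sc <- matrix(rnorm(20), 10, 2)
  bp <- predict_block(ctr, sc)
  for (i in 1:10) {
    for (k in 1:3) {
      d <- sqrt(sum((sc[i, ] - ctr[k, ])^2))
      expect_equal(-unname(bp$score[i, k]), d, tolerance = 1e-12)
    }
    expect_equal(as.character(bp$class[i]),
                 rownames(ctr)[which.max(bp$score[i, ])])
  }
  # a sample at a centroid is assigned that class with score 0
  at <- predict_block(ctr, ctr["b", , drop = FALSE])
  expect_equal(as.character(at$class), "b")
  expect_equal(at$score[1, "b"], 0)
  # equidistant sample goes to the first class in order
  eq <- predict_block(matrix(c(1, -1, 0, 0), 2,
                             dimnames = list(c("p", "q"), NULL)),
                      matrix(c(0, 5), 1))
  expect_equal(as.character(eq$class), "p")
})

test_that("block weights reflect score-outcome correlation", {
  ds <- small_study(seed = 3, separation = 6)
  m <- sgcca(ds$blocks, ds$labels, keepX = 15)
  expect_true(all(m$weights >= 0 & m$weights <= 1))
  expect_identical(block_weights(m), m$weights)
  # a score equal to a dummy column has correlation 1 with it
  dm <- dummy_matrix(ds$labels)
  fake <- m
  fake$scores$mrna <- cbind(dm$y_centered[, 1], dm$y_centered[, 1])
  expect_equal(unname(block_weights(fake)["mrna"]), 1)
})

test_that("weighted vote follows weights, unanimity and tie rules", {
  expect_equal(as.character(weighted_vote(
    list(factor("A", levels = c("A", "B")), factor("B", levels = c("A", "B"))),
    c(0.9, 0.5))), "A")
  # single block: identity
  v <- factor(c("A", "B", "A"), levels = c("A", "B"))
  expect_equal(weighted_vote(list(v), 0.4), v)
  # unanimity wins regardless of weights
  expect_equal(as.character(weighted_vote(
    list(factor("B", levels = c("A", "B")), factor("B", levels = c("A", "B"))),
    c(0.01, 0.01))), "B")
  # exact tie: the higher-weight block's vote wins
  expect_equal(as.character(weighted_vote(
    list(factor("A", levels = c("A", "B")), factor("B", levels = c("A", "B"))),
    c(0.5, 0.5))), "A")
  # equal weights reduce to majority vote
  set.seed(4)
  votes <- lapply(1:5, function(i)
    factor(sample(c("A", "B", "C"), 20, replace = TRUE),
           levels = c("A", "B", "C")))
  wv <- weighted_vote(votes, rep(1, 5))
  vote_mat <- vapply(votes, as.character, character(20))
  for (i in 1:20) {
    tab <- table(factor(vote_mat[i, ], levels = c("A", "B", "C")))
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) {
      expect_equal(as.character(wv[i]), top)      # strict majority wins
    } else {
      expect_true(as.character(wv[i]) %in% top)   # ties stay among the tied
    }
  }
})

test_that("performance metrics match hand-computed cases", {
  y <- factor(c("A", "A", "B", "B"))
  pm <- performance_metrics(y, y)
  expect_equal(pm$accuracy, 1)
  expect_equal(pm$per_class$f1, c(1, 1))
  # degenerate all-one-class prediction
  pm2 <- performance_metrics(y, factor(rep("A", 4), levels = c("A", "B")))
  expect_equal(pm2$accuracy, 0.5)
  expect_equal(pm2$per_class$precision[pm2$per_class$class == "A"], 0.5)
  expect_equal(pm2$per_class$f1[pm2$per_class$class == "B"], 0)
  expect_true("B" %in% pm2$undefined)
  expect_equal(sum(pm2$confusion), 4)
  expect_equal(unname(rowSums(pm2$confusion)), c(2, 2))
  expect_error(performance_metrics(factor(character(0)), factor(character(0))),
               "empty")
})

test_that("AUC equals all-pairs concordance", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.3, 0.8, 0.2), c(1, 0, 0, 1)), 0.5)
  set.seed(5)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    sc <- sample(round(rnorm(n), 2))   # rounded scores force ties
    lb <- rbinom(n, 1, 0.5)
    if (sum(lb) == 0 || sum(lb) == n) next
    a <- roc_auc(sc, lb)
    expect_equal(a, auc_bruteforce(sc, lb), tolerance = 1e-12)
    expect_equal(roc_auc(sc, 1 - lb), 1 - a, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both label values")
})

test_that("per-component AUCs are high for well-separated classes", {
  ds <- small_study(seed = 6, separation = 6)
  m <- sgcca(ds$blocks, ds$labels, keepX = 15)
  auc <- component_auc(m, m$scores, ds$labels)
  expect_gt(mean(auc$mrna), 0.9)
  expect_true(all(unlist(auc) >= 0 & unlist(auc) <= 1))
})

test_that("end-to-end prediction is near-perfect on strong-signal data", {
  ds <- generate_study(sim_config(class_separation = 6, seed = 7))
  sp <- stratified_split(ds$labels, 0.7, seed = 8)
  tr <- match(sp$train, names(ds$labels))
  te <- match(sp$test, names(ds$labels))
  m <- sgcca(lapply(ds$blocks, function(b) b[tr, , drop = FALSE]),
             ds$labels[tr], keepX = 20)
  pred <- predict(m, lapply(ds$blocks, function(b) b[te, , drop = FALSE]))
  expect_gte(performance_metrics(ds$labels[te], pred$class)$accuracy, 0.95)
})
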