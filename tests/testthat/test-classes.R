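# two well-separated portrait blocks plus optional noise
block_portraits <- function(n_per = 4, n_nodes = 40, noise = 0.02, seed = 1) {
  set.seed(seed)
  a <- rnorm(n_nodes); b <- rnorm(n_nodes)
  P <- cbind(replicate(n_per, a + rnorm(n_nodes, sd = noise)),
             replicate(n_per, b + rnorm(n_nodes, sd = noise)))
  colnames(P) <- paste0("s", seq_len(2 * n_per))
  P
}

test_that("portrait correlations are symmetric with unit diagonal", {
  P <- block_portraits()
  r <- portrait_correlation_matrix(P)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, ncol(P)))
  expect_true(all(r >= -1 - 1e-12 & r <= 1 + 1e-12))
  # negation gives -1; hand-computed 3-sample Pearson
  Q <- cbind(x = c(1, 2, 3, 5), y = -c(1, 2, 3, 5), z = c(2, 2, 1, 0))
  rq <- portrait_correlation_matrix(Q)
  expect_equal(rq["x", "y"], -1)
  expect_equal(rq["x", "z"], cov(Q[, "x"], Q[, "z"]) /
                 (sd(Q[, "x"]) * sd(Q[, "z"])))
})

test_that("separable blocks are perfectly partitioned with positive S", {
  P <- block_portraits()
  cls <- discover_classes(P, K = 2, seed = 3)
  lab <- unname(cls$labels)
  expect_equal(length(unique(lab[1:4])), 1)
  expect_equal(length(unique(lab[5:8])), 1)
  expect_false(lab[1] == lab[5])
  expect_true(all(cls$S > 0))
})

test_that("K equal to the sample count degenerates to singletons", {
  P <- block_portraits(n_per = 3, noise = 0.5, seed = 5)
  n <- ncol(P)
  cls <- discover_classes(P, K = n, seed = 2)
  expect_equal(sort(unname(cls$labels)), 1:n)
  # every portrait correlates perfectly with its own (singleton) centroid
  expect_true(all(is.finite(cls$S)))
  expect_lte(cls$iterations, 2)
})

test_that("silhouette scores match the correlation-gap definition", {
  set.seed(9)
  P <- matrix(rnorm(40 * 6), 40, 6)
  colnames(P) <- paste0("s", 1:6)
  labels <- c(1, 1, 1, 2, 2, 2)
  S <- silhouette_scores(P, labels)
  for (i in 1:6) {
    c1 <- rowMeans(P[, labels == 1, drop = FALSE])
    c2 <- rowMeans(P[, labels == 2, drop = FALSE])
    own <- if (labels[i] == 1) cor(P[, i], c1) else cor(P[, i], c2)
    oth <- if (labels[i] == 1) cor(P[, i], c2) else cor(P[, i], c1)
    expect_equal(unname(S[i]), own - oth, tolerance = 1e-12)
  }
})

test_that("silhouette boundary cases give 0 and 1", {
  set.seed(4)
  base <- rnorm(30)
  other <- rnorm(30)
  cent <- cbind(a = base, b = other)
  # sample equally correlated with both centroids scores 0
  P0 <- cbind(x = base + other)
  s0 <- silhouette_scores(P0, labels = "a",
                          centroids = cbind(a = base + other,
                                            b = base + other))
  expect_equal(unname(s0), 0)
  # sample identical to its centroid and uncorrelated to the other
  ortho <- stats::residuals(lm(other ~ base))
  s1 <- silhouette_scores(cbind(x = base), labels = "a",
                          centroids = cbind(a = base, b = ortho))
  expect_equal(unname(s1), 1, tolerance = 1e-10)
})

test_that("class relabeling leaves silhouette scores unchanged", {
  P <- block_portraits(noise = 0.3, seed = 7)
  labels <- rep(c(1, 2), each = 4)
  S1 <- silhouette_scores(P, labels)
  S2 <- silhouette_scores(P, c("B", "A")[labels])
  expect_equal(unname(S1), unname(S2))
})

test_that("refinement never decreases mean S and always terminates", {
  for (s in 1:12) {
    set.seed(s)
    n <- sample(15:60, 1)
    K <- sample(2:5, 1)
    P <- matrix(rnorm(30 * n), 30, n) +
      outer(rnorm(30), sample(c(-1, 1), n, TRUE) * runif(n))
    colnames(P) <- paste0("s", seq_len(n))
    cls <- suppressMessages(discover_classes(P, K = K, seed = s))
    expect_true(all(diff(cls$mean_s_history) >= -1e-10))
    expect_lt(cls$iterations, 100)
  }
})

test_that("bootstrap stability is ~100% for separable blocks and reproducible", {
  P <- block_portraits(n_per = 6, seed = 8)
  bs1 <- suppressMessages(bootstrap_stability(P, K = 2, B = 20, seed = 3))
  bs2 <- suppressMessages(bootstrap_stability(P, K = 2, B = 20, seed = 3))
  expect_identical(bs1$stability, bs2$stability)
  expect_gte(bs1$stability, 99)
})

test_that("pure-noise portraits yield chance-level stability", {
  set.seed(12)
  P <- matrix(rnorm(50 * 24), 50, 24)
  colnames(P) <- paste0("s", 1:24)
  bs <- suppressMessages(bootstrap_stability(P, K = 2, B = 30, seed = 12))
  # permutation estimate of the chance agreement of the matching scheme:
  # relabel in-bag samples randomly with the reference class proportions.
  # A fixed noise dataset retains reproducible correlation structure under
  # resampling, so the permutation value is a floor; stability must sit in
  # the band between that floor and the separable-case ~100%.
  ref <- suppressMessages(discover_classes(P, K = 2, seed = 12))
  set.seed(99)
  chance <- mean(replicate(200, {
    idx <- sample(24, replace = TRUE)
    rnd <- sample(unname(ref$labels))[idx]
    max(mean(rnd == ref$labels[idx]), mean((3 - rnd) == ref$labels[idx]))
  })) * 100
  expect_gte(bs$stability, chance - 5)
  expect_lt(bs$stability, 90)
})

test_that("correlation networks follow threshold and knn rules", {
  P <- block_portraits(n_per = 2, noise = 0.4, seed = 10)
  r <- portrait_correlation_matrix(P)
  expect_equal(nrow(correlation_network(r, "threshold", 1.0)), 0)
  full <- correlation_network(r, "threshold", -1)
  expect_equal(nrow(full), choose(ncol(P), 2))
  # knn k=1 on a 3-sample toy against hand-ranked correlations
  Q <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 5), c = c(4, 3, 2, 1))
  rq <- portrait_correlation_matrix(Q)
  net <- correlation_network(rq, "knn", 1)
  # a's and b's nearest neighbour is each other; c's is whichever of a/b
  # ranks higher
  expect_true(any(net$from == "a" & net$to == "b"))
  cbest <- c("a", "b")[which.max(c(rq["c", "a"], rq["c", "b"]))]
  expect_true(any((net$from == cbest & net$to == "c") |
                    (net$from == "c" & net$to == cbest)))
})
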