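test_that("FNC is the Pearson correlation matrix of the time courses", {
  tcs <- cbind(sin(1:50), sin(1:50), cos(1:50))
  f <- fnc(tcs)
  expect_equal(f[1, 2], 1.0)
  expect_true(isSymmetric(f))
  expect_equal(diag(f), rep(1, 3))

  t2 <- cbind(sin(2 * pi * (1:100) / 10), cos(2 * pi * (1:100) / 10))
  expect_lt(abs(fnc(t2)[1, 2]), 1e-10)

  # worked three-variable case against closed-form correlations
  set.seed(1)
  z <- rnorm(2000); e1 <- rnorm(2000); e2 <- rnorm(2000)
  x <- cbind(z, z + e1, e2)
  expect_equal(fnc(x), cor(x), tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(fnc(cbind(rnorm(10), rep(1, 10))), "network 2")
})

test_that("Q evaluation matches the literal sum-over-pairs oracle", {
  q_oracle <- function(W, part) {
    W <- as.matrix(W); diag(W) <- 0
    Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
    sp <- rowSums(Wp); sn <- rowSums(Wn)
    vp <- sum(sp); vn <- sum(sn)
    q <- 0
    for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W))) {
      if (part[i] != part[j]) next
      if (vp > 0) q <- q + (Wp[i, j] - sp[i] * sp[j] / vp) / vp
      if (vn > 0) q <- q - (Wn[i, j] - sn[i] * sn[j] / vn) / (vp + vn)
    }
    q
  }
  set.seed(2)
  for (rep in 1:10) {
    W <- matrix(rnorm(64), 8, 8); W <- (W + t(W)) / 2
    part <- sample(1:3, 8, TRUE)
    expect_equal(modularity_q(W, part), q_oracle(W, part), tolerance = 1e-12)
  }

  # two disjoint unit triangles: the classic hand value
  W <- matrix(0, 6, 6)
  W[1, 2] <- W[2, 3] <- W[1, 3] <- 1
  W[4, 5] <- W[5, 6] <- W[4, 6] <- 1
  W <- W + t(W)
  expect_equal(modularity_q(W, c(1, 1, 1, 2, 2, 2)), 0.5, tolerance = 1e-12)
  expect_equal(modularity_q(W, rep(1, 6)), 0, tolerance = 1e-12)
})

test_that("leading-eigenvector partitioning recovers planted structure and
           matches exhaustive search", {
  W <- matrix(0, 6, 6)
  W[1, 2] <- W[2, 3] <- W[1, 3] <- 1
  W[4, 5] <- W[5, 6] <- W[4, 6] <- 1
  W <- W + t(W)
  mp <- modularity_partition(W)
  expect_equal(mp$Q, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(mp$partition)), 2)

  # planted 2-block matrix: exact recovery, Q equal to the exhaustive
  # 2-partition maximum
  set.seed(3)
  N <- 10
  block <- rep(1:2, each = 5)
  W2 <- matrix(0.05, N, N)
  W2[block == 1, block == 1] <- 0.8
  W2[block == 2, block == 2] <- 0.8
  W2 <- (W2 + t(W2)) / 2; diag(W2) <- 0
  mp2 <- modularity_partition(W2)
  expect_equal(length(unique(mp2$partition)), 2)
  expect_true(all(mp2$partition[1:5] == mp2$partition[1]))
  expect_true(all(mp2$partition[6:10] == mp2$partition[6]))

  best <- -Inf
  for (code in 1:(2^(N - 1) - 1)) {  # all non-trivial 2-partitions
    part <- c(1, as.integer(intToBits(code))[1:(N - 1)] + 1L)
    best <- max(best, modularity_q(W2, part))
  }
  expect_gte(mp2$Q, best - 1e-9)

  # all-zero matrix: single community, Q = 0
  mp0 <- modularity_partition(matrix(0, 4, 4))
  expect_equal(mp0$partition, rep(1L, 4))
  expect_equal(mp0$Q, 0)

  # deterministic
  expect_identical(modularity_partition(W2), modularity_partition(W2))
})

test_that("AMI is 1 for relabelings, ~0 for independent partitions, and
           matches an external reference", {
  p <- c(1, 1, 1, 2, 2, 3, 3, 3, 3, 1)
  expect_equal(ami(p, p), 1.0)
  relab <- c(3, 3, 3, 1, 1, 2, 2, 2, 2, 3)
  expect_equal(ami(p, relab), 1.0)

  # frozen reference values (scikit-learn adjusted_mutual_info_score, max
  # normalization)
  q <- c(2, 2, 1, 1, 3, 3, 3, 1, 3, 2)
  expect_equal(ami(p, q), 0.2652574, tolerance = 1e-6)
  expect_equal(ami(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5, tolerance = 1e-9)

  expect_equal(ami(p, q), ami(q, p), tolerance = 1e-12)
  expect_error(ami(1:3, 1:4), "length")

  set.seed(4)
  vals <- vapply(1:100, function(i) {
    ami(sample(1:4, 100, TRUE), sample(1:4, 100, TRUE))
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("sparsity thresholding keeps the top pairs and all cutoff ties", {
  W <- matrix(0, 4, 4)
  W[upper.tri(W)] <- c(0.9, 0.8, 0.3, -0.7, 0.2, 0.1)
  W <- W + t(W); diag(W) <- 1
  th <- threshold_sparsity(W, 0.5)
  kept <- sort(th[upper.tri(th)][th[upper.tri(th)] > 0], decreasing = TRUE)
  expect_equal(kept, c(0.9, 0.8, 0.7))
  expect_equal(diag(th), rep(0, 4))

  full <- threshold_sparsity(W, 1)
  expect_equal(full[upper.tri(full)], abs(W[upper.tri(W)]))

  # ties at the cutoff are all kept
  Wt <- matrix(0, 4, 4)
  Wt[upper.tri(Wt)] <- c(0.9, 0.5, 0.5, 0.5, 0.2, 0.1)
  Wt <- Wt + t(Wt)
  tht <- threshold_sparsity(Wt, 0.5)
  expect_equal(sum(tht[upper.tri(tht)] > 0), 4)
})

test_that("weighted graph metrics match hand computations", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  gm <- graph_metrics(k4)
  expect_equal(gm$node_strength, 3)
  expect_equal(gm$clustering, 1)
  expect_equal(gm$global_eff, 1)
  expect_equal(gm$local_eff, 1)

  # two disconnected unit edges: 2 of 6 pairs reachable at distance 1
  two <- matrix(0, 4, 4)
  two[1, 2] <- two[2, 1] <- 1; two[3, 4] <- two[4, 3] <- 1
  expect_equal(graph_metrics(two)$global_eff, 2 / 6, tolerance = 1e-12)

  # path A-B-C
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  gp <- graph_metrics(path)
  expect_equal(gp$node_strength, (1 + 2 + 1) / 3, tolerance = 1e-12)
  expect_equal(gp$global_eff, (1 + 1 + 0.5) / 3, tolerance = 1e-12)
})

test_that("fnc_graph composes connectivity, partitioning, and metrics", {
  set.seed(5)
  z1 <- rnorm(120); z2 <- rnorm(120)
  tcs <- cbind(z1 + rnorm(120, sd = .4), z1 + rnorm(120, sd = .4),
               z2 + rnorm(120, sd = .4), z2 + rnorm(120, sd = .4))
  fg <- fnc_graph(tcs, sparsity = 0.5)
  expect_s3_class(fg, "fnc_graph")
  expect_equal(length(unique(fg$partition)), 2)
  expect_equal(fg$partition[1], fg$partition[2])
  expect_equal(fg$partition[3], fg$partition[4])
  expect_gt(fg$Q, 0)
})
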