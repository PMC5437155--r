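test_that("greedy matching picks global maxima and handles shape edge cases", {
  sim <- matrix(0.1, 3, 3); diag(sim) <- 0.9
  mt <- greedy_match(sim)
  expect_equal(mt$pairs$est, mt$pairs$template)

  # greedy differs from the optimal assignment by construction
  mt2 <- greedy_match(matrix(c(0.9, 0.85, 0.8, 0.1), 2, 2))
  expect_equal(mt2$pairs$est, c(1L, 2L))
  expect_equal(mt2$pairs$template, c(1L, 2L))
  expect_equal(sum(mt2$pairs$similarity), 1.0)  # optimal total would be 1.65

  mt3 <- greedy_match(matrix(runif(6), 3, 2))
  expect_equal(nrow(mt3$pairs), 2)
  expect_length(mt3$unmatched_est, 1)

  mt0 <- greedy_match(matrix(numeric(0), 0, 0))
  expect_equal(nrow(mt0$pairs), 0)
})

test_that("greedy matching equals the literal delete-and-repeat oracle", {
  oracle <- function(sim) {
    pairs <- NULL
    rows <- seq_len(nrow(sim)); cols <- seq_len(ncol(sim))
    while (length(rows) && length(cols)) {
      best <- -Inf; bi <- bj <- NA
      for (i in rows) for (j in cols) {
        if (sim[i, j] > best) { best <- sim[i, j]; bi <- i; bj <- j }
      }
      pairs <- rbind(pairs, c(bi, bj))
      rows <- setdiff(rows, bi); cols <- setdiff(cols, bj)
    }
    pairs
  }
  set.seed(42)
  for (rep in 1:20) {
    sim <- matrix(runif(36), 6, 6)
    mt <- greedy_match(sim)
    orc <- oracle(sim)
    expect_equal(as.matrix(mt$pairs[, 1:2]), orc, ignore_attr = TRUE)
  }
})

test_that("accuracy is the absolute Pearson correlation", {
  x <- c(1, 2, 3, 4)
  expect_equal(accuracy(x, x), 1.0)
  expect_equal(accuracy(x, -x), 1.0)
  expect_equal(accuracy(x, c(1, 2, 3, 5)), 0.9827076, tolerance = 1e-6)
  expect_error(accuracy(rep(1, 4), x), "constant")
})

test_that("paired t-test matches the textbook formula", {
  tt <- paired_ttest(c(1, 2, 3, 4), c(2, 3, 5, 7))
  expect_equal(tt$t, -3.656, tolerance = 1e-3)
  expect_equal(tt$df, 3)

  set.seed(3)
  for (rep in 1:100) {
    n <- sample(3:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    d <- a - b
    t_oracle <- mean(d) / (sd(d) / sqrt(n))
    p_oracle <- 2 * pt(-abs(t_oracle), n - 1)
    tt <- paired_ttest(a, b)
    expect_equal(tt$t, t_oracle, tolerance = 1e-12)
    expect_equal(tt$p, p_oracle, tolerance = 1e-12)
    expect_equal(tt$t, -paired_ttest(b, a)$t, tolerance = 1e-12)
  }

  a <- rnorm(6)
  expect_gt(paired_ttest(a + 1 + rnorm(6, sd = 1e-4), a)$t, 100)
  expect_error(paired_ttest(a, a), "zero-variance")
})

test_that("Bonferroni flags use the family-size-adjusted threshold", {
  expect_equal(bonferroni(c(0.004, 0.2), 0.05), c(TRUE, FALSE))
  expect_equal(bonferroni(0.049, 0.05), TRUE)
  expect_equal(bonferroni(rep(0.006, 10), 0.05), rep(FALSE, 10))
  expect_equal(bonferroni(numeric(0)), logical(0))
  # agrees with p.adjust
  set.seed(5)
  p <- runif(25)
  expect_equal(bonferroni(p, 0.05), p.adjust(p, "bonferroni") < 0.05)
})

test_that("scoring ground truth against itself yields perfect accuracy and
           is invariant to component shuffling", {
  sm <- gen_small(M = 4, C = 3, T_len = 50, cnr = 5, seed = 17)
  fake <- function(perm = 1:3) {
    structure(list(
      method = "fake", model_order = 3,
      group_maps = zscore(Reduce(`+`, lapply(sm$truth, `[[`, "maps")) / 4)[perm, , drop = FALSE],
      subject_maps = lapply(sm$truth, function(g) zscore(g$maps)[perm, , drop = FALSE]),
      subject_tcs = lapply(sm$truth, function(g) g$tcs[, perm, drop = FALSE])
    ), class = "decomposition_result")
  }
  sc <- score_experiment(list(a = fake(), b = fake()), sm$truth)
  expect_true(all(abs(sc$tables$a$spatial - 1) < 1e-10))
  expect_true(all(abs(sc$tables$a$temporal - 1) < 1e-10))
  # identical methods: zero-variance differences surface as "no difference"
  expect_true(all(sc$tests$p == 1))
  expect_true(all(sc$tests$t == 0))

  sc_perm <- score_experiment(list(a = fake(c(3, 1, 2)), b = fake()),
                              sm$truth)
  expect_equal(sc_perm$tables$a$spatial, sc$tables$a$spatial,
               tolerance = 1e-12)
})

test_that("scoring with a subject-unique source matches exactly one extra
           component per subject", {
  run <- cached("run_exp3", run_sim_setting("exp3_unique", seed = 301,
                                            n_components = 8,
                                            by = "component"))
  for (tb in run$score$tables) {
    expect_equal(ncol(tb$spatial), 8)          # 7 common + 1 unique column
    expect_true(all(is.finite(tb$spatial[, 8])))
    expect_equal(length(tb$match$unmatched_est), 1)
  }
  expect_equal(nrow(run$score$tests), 16)      # 8 components x 2 domains
})
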