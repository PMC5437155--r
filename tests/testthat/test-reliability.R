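test_that("one-sample t maps with BH-FDR separate signal from null", {
  set.seed(1)
  strong <- matrix(1 + rnorm(20 * 1000, sd = 0.01), 20, 1000)
  res <- one_sample_t_fdr(strong, q = 0.01)
  expect_gte(mean(res$mask), 0.99)

  # global null: expected surviving fraction ~ 0
  fr <- vapply(1:50, function(s) {
    set.seed(s)
    mean(one_sample_t_fdr(matrix(rnorm(10 * 1000), 10, 1000), q = 0.01)$mask)
  }, numeric(1))
  expect_lte(mean(fr), 0.01)

  # the BH step-up rule: with p = (.001, .008, .039, .041) at q = .05 the
  # largest k with p(k) <= k q / m is k = 4, so all four survive
  p <- c(0.001, 0.008, 0.039, 0.041)
  expect_equal(p.adjust(p, "BH") <= 0.05, rep(TRUE, 4))

  # zero-variance voxels never survive
  const <- cbind(matrix(rnorm(12 * 5), 12, 5), rep(1, 12) * 0)
  r2 <- one_sample_t_fdr(const, q = 0.05)
  expect_equal(r2$p[6], 1)
})

test_that("one-way ICC matches hand ANOVA, clamps, and is affine-stable", {
  expect_equal(icc_oneway(c(0, 10), c(0, 10))$icc, 1.0)

  r <- icc_oneway(c(1, 2, 3), c(1.5, 2.5, 3.5))
  expect_equal(r$sigma_e2, 0.125, tolerance = 1e-12)   # MSW by hand
  expect_equal(r$icc, 0.9375 / (0.9375 + 0.125), tolerance = 1e-12)
  expect_equal(r$icc, 0.88235, tolerance = 1e-4)

  # negative variance component clamps to zero
  r2 <- icc_oneway(c(1, 2, 3), c(3, 2, 1))
  expect_equal(r2$sigma_p2, 0)
  expect_equal(r2$icc, 0)

  expect_error(icc_oneway(1, 1), "n >= 2")

  set.seed(2)
  x1 <- rnorm(10); x2 <- x1 + rnorm(10, sd = 0.3)
  base <- icc_oneway(x1, x2)$icc
  expect_equal(icc_oneway(x1 + 5, x2 + 5)$icc, base, tolerance = 1e-12)
  expect_equal(icc_oneway(3 * x1, 3 * x2)$icc, base, tolerance = 1e-12)
})

test_that("ICC estimation recovers generative variance ratios", {
  # criterion-style parameter recovery at n = 25, k = 2
  set.seed(7)
  for (sp in c(0.2, 0.5, 1)) {
    for (se in c(0.2, 0.5)) {
      true_icc <- sp^2 / (sp^2 + se^2)
      est <- vapply(1:200, function(i) {
        subj <- rnorm(25, sd = sp)
        icc_oneway(subj + rnorm(25, sd = se), subj + rnorm(25, sd = se))$icc
      }, numeric(1))
      # unbiased within Monte-Carlo error
      expect_lt(abs(mean(est) - true_icc), 0.05)
    }
  }
})

test_that("network reliability averages voxelwise ICC inside the mask", {
  set.seed(3)
  V <- 200; n <- 12
  subj <- matrix(rnorm(n * V), n, V)
  scans <- list(subj + matrix(rnorm(n * V, sd = 0.1), n, V),
                subj,
                subj)  # scan 2 identical to scan 3
  mask <- rep(TRUE, V)
  expect_equal(network_reliability(scans, mask, "short"), 1.0)

  # independent scans: near-zero reliability
  null_vals <- vapply(1:50, function(s) {
    set.seed(s + 100)
    sc <- lapply(1:3, function(i) matrix(rnorm(10 * 50), 10, 50))
    network_reliability(sc, rep(TRUE, 50), "short")
  }, numeric(1))
  expect_lte(mean(null_vals), 0.2)

  # out-of-mask voxels are ignored
  mask2 <- c(rep(TRUE, 100), rep(FALSE, 100))
  base <- network_reliability(scans, mask2, "long")
  scr <- lapply(scans, function(s) { s[, 101:200] <- rnorm(n * 100); s })
  expect_equal(network_reliability(scr, mask2, "long"), base,
               tolerance = 1e-12)

  expect_error(network_reliability(scans, rep(FALSE, V), "short"), "mask")
})

test_that("connectivity ICC works elementwise with known generative values", {
  set.seed(4)
  E <- 150; n <- 25
  f <- matrix(rnorm(n * E), n, E)
  stacks <- list(f, f, f)
  expect_true(all(connectivity_icc(stacks, "short") == 1))

  # a connectivity constant across subjects has no inter-subject variance
  f2 <- f; f2[, 1] <- 0
  st2 <- list(f2, f2, f2)
  expect_equal(connectivity_icc(st2, "short")[1], 0)

  # generative recovery: subject SD 0.3, error SD 0.1 -> ICC = 0.9
  subj <- matrix(rnorm(n * E, sd = 0.3), n, E)
  mk <- function() subj + matrix(rnorm(n * E, sd = 0.1), n, E)
  icc <- connectivity_icc(list(mk(), mk(), mk()), "short")
  expect_lt(abs(median(icc) - 0.9), 0.1)
})
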