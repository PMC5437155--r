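test_that("base maps are normalized, compact, and nearly non-overlapping", {
  one <- make_base_maps(1, c(148, 148), seed = 3)
  expect_equal(max(one), 1.0)
  expect_true(all(one >= 0 & one <= 1))

  maps <- make_base_maps(8, c(148, 148), seed = 7)
  expect_equal(dim(maps), c(8, 148 * 148))
  pc <- abs(cor(t(maps)))
  diag(pc) <- 0
  expect_lt(max(pc), 0.3)

  expect_identical(maps, make_base_maps(8, c(148, 148), seed = 7))
  expect_error(make_base_maps(80, c(148, 148), seed = 1), "overlap|place")
})

test_that("map perturbation translates, rotates, and scales about centroid", {
  m <- matrix(make_base_maps(1, c(60, 60), seed = 2, sigma = 3), 60, 60,
              byrow = TRUE)
  expect_lt(max(abs(perturb_map(m, c(0, 0), 0, 1) - m)), 1e-6)

  centroid <- function(mm) {
    c(sum(row(mm) * mm), sum(col(mm) * mm)) / sum(mm)
  }
  shifted <- perturb_map(m, translation = c(5, 0), rotation = 0, spread = 1)
  d <- centroid(shifted) - centroid(m)
  expect_lt(abs(d[2] - 5), 0.5)  # dx moves the column coordinate
  expect_lt(abs(d[1]), 0.5)

  # rotation of an elongated blob turns its principal axis by ~90 degrees
  xx <- outer(seq_len(60), rep(1, 60)); yy <- t(xx)
  elong <- exp(-((xx - 30)^2 / (2 * 9^2) + (yy - 30)^2 / (2 * 2^2)))
  principal_axis <- function(mm) {
    w <- mm / sum(mm)
    mu <- c(sum(xx * w), sum(yy * w))
    cov <- matrix(c(sum((xx - mu[1])^2 * w), sum((xx - mu[1]) * (yy - mu[2]) * w),
                    sum((xx - mu[1]) * (yy - mu[2]) * w), sum((yy - mu[2])^2 * w)), 2)
    eigen(cov, symmetric = TRUE)$vectors[, 1]
  }
  rot <- perturb_map(elong, c(0, 0), rotation = 90, spread = 1)
  ax1 <- principal_axis(elong); ax2 <- principal_axis(rot)
  expect_lt(abs(sum(ax1 * ax2)), 0.1)  # near-orthogonal axes

  # spreading scales the mass footprint
  spread <- perturb_map(m, c(0, 0), 0, spread = 2)
  expect_gt(sum(spread > 0.5), 2 * sum(m > 0.5))
})

test_that("time courses are standardized, smooth, and seed-independent", {
  tc <- make_tcs(3, 150, seed = 1)
  expect_equal(dim(tc), c(150, 3))
  expect_true(all(abs(colMeans(tc)) <= 1e-10))
  expect_true(all(abs(apply(tc, 2, var) - 1) <= 1e-10))
  lag1 <- vapply(1:3, function(j) cor(tc[-1, j], tc[-150, j]), numeric(1))
  expect_true(all(lag1 > 0.3))

  # across seeds the processes are unrelated on average
  rs <- vapply(1:50, function(s) {
    a <- make_tcs(1, 150, seed = s)
    b <- make_tcs(1, 150, seed = s + 5000)
    abs(cor(a, b))
  }, numeric(1))
  expect_lt(mean(rs), 0.2)
})

test_that("Rician corruption hits the requested CNR and is deterministic", {
  maps <- make_base_maps(3, c(30, 30), seed = 4, sigma = 2)
  tcs <- make_tcs(3, 100, seed = 5)
  clean <- tcs %*% maps

  expect_lt(max(abs(add_rician_noise(clean, Inf, 100) - clean - 100)), 1e-9)
  expect_error(add_rician_noise(clean, -1), "positive")

  noisy <- add_rician_noise(clean, cnr = 2, baseline = 100, seed = 6)
  expect_identical(noisy, add_rician_noise(clean, cnr = 2, baseline = 100,
                                           seed = 6))
  sds <- sqrt(colMeans(clean^2) - colMeans(clean)^2)
  in_src <- sds > 0.1 * max(sds)
  sigma_target <- mean(sds[in_src]) / 2
  resid <- (noisy - clean - 100)[, !in_src]
  expect_lt(abs(sd(resid) / sigma_target - 1), 0.1)
})

test_that("experiment presets reproduce the study design", {
  g1 <- cached("gen_exp1_cnr1", generate_experiment("exp1_quality", seed = 5,
                                                    cnr = 1))
  expect_length(g1$datasets, 10)
  expect_equal(dim(g1$datasets[[1]]$data), c(150, 148 * 148))
  expect_false(anyNA(g1$datasets[[3]]$data))
  # linear mixture identity holds for the ground truth
  expect_equal(g1$truth[[1]]$tcs %*% g1$truth[[1]]$maps,
               g1$truth[[1]]$tcs %*% g1$truth[[1]]$maps)

  g2 <- cached("gen_exp2", generate_experiment("exp2_varied_sources",
                                               seed = 5))
  expect_equal(vapply(g2$truth, function(g) nrow(g$maps), integer(1)),
               c(rep(8L, 5), rep(7L, 5)))

  expect_error(generate_experiment("nope", seed = 1), "unknown preset")
})

test_that("subject-unique sources vary across subjects, common ones do not", {
  g3 <- cached("gen_exp3", generate_experiment("exp3_unique", seed = 5))
  expect_true(all(vapply(g3$truth, function(g) sum(g$labels == "unique"),
                         integer(1)) == 1L))
  cross_cor <- function(j) {
    vals <- c()
    for (a in 1:9) for (b in (a + 1):10) {
      vals <- c(vals, abs(cor(g3$truth[[a]]$maps[j, ], g3$truth[[b]]$maps[j, ])))
    }
    mean(vals)
  }
  common <- vapply(1:7, cross_cor, numeric(1))
  expect_true(all(common > 0.7))
  # two independently placed blobs of SD ~15 px on this grid overlap a
  # little by chance, so the cross-subject correlation is small but not zero
  expect_lt(cross_cor(8), 0.25)
  expect_lt(cross_cor(8), min(common) - 0.4)
})

test_that("generation is deterministic given (preset, seed)", {
  a <- generate_experiment("exp1_quantity", seed = 9, n_timepoints = 40)
  b <- generate_experiment("exp1_quantity", seed = 9, n_timepoints = 40)
  expect_identical(a$datasets[[2]]$data, b$datasets[[2]]$data)
  expect_identical(a$truth[[7]]$maps, b$truth[[7]]$maps)
  expect_equal(nrow(a$datasets[[1]]$data), 40)
})
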