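# Shared fixtures, built in code. Small-scale multi-subject datasets for
# plumbing tests, synthetic SCV problems for the IVA oracles, and a cache so
# expensive full-scale runs are computed once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small multi-subject blob simulation (fast plumbing scale)
gen_small <- function(M = 4, C = 3, grid = c(24, 24), T_len = 60, cnr = 3,
                      seed = 1L, translation_sd = 1, spread = 1) {
  set.seed(seed)
  # tiny grids leave little room between blobs; allow moderate overlap
  base <- make_base_maps(C, grid, seed = seed, sigma = 2, overlap_cap = 0.5)
  datasets <- list(); truth <- list()
  for (m in seq_len(M)) {
    maps <- t(vapply(seq_len(C), function(i) {
      perturb_map(base[i, ], translation = rnorm(2, 0, translation_sd),
                  rotation = rnorm(1, 0, 3), spread = spread, grid = grid)
    }, numeric(prod(grid))))
    tcs <- make_tcs(C, T_len, seed = seed + 100 * m)
    clean <- tcs %*% maps
    data <- add_rician_noise(clean, cnr = cnr, baseline = 50,
                             seed = seed + 200 * m)
    datasets[[m]] <- data
    truth[[m]] <- structure(list(maps = maps, tcs = tcs,
                                 labels = rep("common", C)),
                            class = "ground_truth")
  }
  list(datasets = datasets, truth = truth, grid = grid)
}

# Synthetic SCV problem: M datasets of k components whose within-SCV
# cross-subject correlations average `rho`; super-Gaussian marginals if
# laplace. The per-SCV correlations are deliberately distinct (spread around
# `rho`): Gaussian SCVs with identical correlation profiles are not
# identifiable (any rotation applied to all subjects at once leaves the
# joint distribution unchanged).
gen_scv <- function(M = 3, k = 4, V = 5000, rho = 0.8, seed = 1L,
                    laplace = FALSE) {
  set.seed(seed)
  rhos <- pmin(pmax(rho + seq(-0.12, 0.12, length.out = k), 0.02), 0.95)
  S <- vector("list", M)
  for (m in seq_len(M)) S[[m]] <- matrix(0, k, V)
  for (l in seq_len(k)) {
    z <- rnorm(V)
    scale_v <- if (laplace) sqrt(rexp(V)) else rep(1, V)
    for (m in seq_len(M)) {
      y <- (sqrt(rhos[l]) * z + sqrt(1 - rhos[l]) * rnorm(V)) * scale_v
      S[[m]][l, ] <- y / sd(y)
    }
  }
  A <- lapply(seq_len(M), function(m) qr.Q(qr(matrix(rnorm(k * k), k, k))))
  X <- Map(function(a, s) a %*% s, A, S)
  # exact row whitening so the reduced-data contract of iva_g holds
  wh <- lapply(X, function(x) {
    xc <- x - rowMeans(x)
    e <- eigen(tcrossprod(xc) / ncol(xc), symmetric = TRUE)
    Wh <- diag(1 / sqrt(e$values)) %*% t(e$vectors)
    list(X = Wh %*% xc, Wh = Wh)
  })
  list(reduced = lapply(wh, `[[`, "X"),
       A_eff = Map(function(w, a) w$Wh %*% a, wh, A),
       sources = S)
}
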