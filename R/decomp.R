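#' PCA reduction and whitening of one subject's data
#'
#' Removes each voxel's temporal mean and projects the time dimension onto
#' the top `k` principal components, returning whitened rows (zero temporal
#' covariance, unit variance in the population convention, i.e. the second
#' moment over voxels divided by V is the identity).
#'
#' @param data matrix (T x V), time by voxels.
#' @param k number of components to retain; must not exceed the rank of the
#'   (voxel-centered) data.
#' @return object of class `reduced_data`: `reduced` (k x V whitened rows),
#'   `whitening` (k x T), `dewhitening` (T x k), `col_means` (length V),
#'   `retained_variance` (fraction of temporal variance kept).
#' @export
pca_reduce <- function(data, k) {
  stopifnot(is.matrix(data), k >= 1)
  V <- ncol(data)
  mu <- colMeans(data)
  dc <- sweep(data, 2, mu)
  Ct <- tcrossprod(dc) / V
  eg <- eigen(Ct, symmetric = TRUE)
  vals <- eg$values
  rank <- sum(vals > max(vals) * 1e-10)
  if (k > rank) {
    stop("k = ", k, " exceeds the data rank (", rank, ")")
  }
  lam <- vals[seq_len(k)]
  E <- eg$vectors[, seq_len(k), drop = FALSE]
  whitening <- diag(1 / sqrt(lam), k) %*% t(E)
  dewhitening <- E %*% diag(sqrt(lam), k)
  structure(list(
    reduced = whitening %*% dc,
    whitening = whitening,
    dewhitening = dewhitening,
    col_means = mu,
    eigenvalues = vals,
    retained_variance = sum(lam) / sum(pmax(vals, 0))
  ), class = "reduced_data")
}

# Whiten with zero-mean rows: PCA reduction followed by row (voxel-mean)
# centering and re-whitening, so that y = w'X has exactly zero mean and unit
# population variance for any unit vector w. `back` maps component space back
# to the (centered) original time dimension.
whiten_rows <- function(data, k) {
  pr <- pca_reduce(data, k)
  X1 <- pr$reduced
  rmu <- rowMeans(X1)
  X1c <- X1 - rmu
  C2 <- tcrossprod(X1c) / ncol(X1c)
  eg <- eigen(C2, symmetric = TRUE)
  if (any(eg$values <= 0)) stop("degenerate whitening: data rank too low")
  Wh2 <- diag(1 / sqrt(eg$values), k) %*% t(eg$vectors)
  list(X = Wh2 %*% X1c,
       back = pr$dewhitening %*% eg$vectors %*% diag(sqrt(eg$values), k),
       col_means = pr$col_means,
       retained_variance = pr$retained_variance)
}

#' Infomax independent component analysis
#'
#' Natural-gradient Infomax with the logistic nonlinearity (suited to
#' super-Gaussian spatial sources). Each epoch sweeps minibatches over a
#' random permutation of the samples; the learning rate is annealed by 0.98
#' when the update direction turns sharply between epochs, and a weight
#' blow-up restarts from the initial weights at a reduced rate.
#'
#' @param whitened matrix (k x V) with whitened rows.
#' @param seed integer seed for the random orthogonal initialisation and the
#'   epoch permutations.
#' @param lr initial learning rate; default `0.015 / log(k)` (GIFT-style).
#' @param tol convergence tolerance on the squared weight change per epoch.
#' @param max_iter maximum number of epochs.
#' @param block minibatch size; 0 picks `min(5 log V, 0.3 V)`.
#' @return list with `unmixing` (k x k; components = unmixing %*% whitened),
#'   `loglik` (per-epoch trace), `converged`, `iterations`.
#' @export
infomax <- function(whitened, seed = 1L, lr = NULL, tol = 1e-6,
                    max_iter = 512L, block = 0L) {
  k <- nrow(whitened)
  if (is.null(lr)) lr <- 0.015 / max(log(k), 1)
  W0 <- with_seed(seed, {
    qr.Q(qr(matrix(rnorm(k * k), k, k)))
  })
  fit <- cpp_infomax(whitened, W0, lr, tol, as.integer(max_iter),
                     as.integer(block),
                     as.integer(seed %% .Machine$integer.max))
  if (!fit$converged) {
    warning("Infomax did not converge in ", max_iter,
            " iterations; returning best iterate")
  }
  list(unmixing = fit$W, loglik = fit$loglik, converged = fit$converged,
       iterations = fit$iterations)
}

# flip rows of `maps` (and matching columns of `mixing`) so map skewness >= 0
skew_flip <- function(maps, mixing = NULL) {
  for (i in seq_len(nrow(maps))) {
    m <- maps[i, ]
    sk <- mean((m - mean(m))^3) / (sd(m)^3)
    if (sk < 0) {
      maps[i, ] <- -maps[i, ]
      if (!is.null(mixing)) mixing[, i] <- -mixing[, i]
    }
  }
  list(maps = maps, mixing = mixing)
}

#' Group-level spatial ICA by temporal concatenation
#'
#' Subject-level PCA to `G1` components each, concatenation of the reduced
#' data along the (reduced) time dimension, group-level PCA to `G2`, and
#' Infomax ICA. Group maps are z-scored over voxels and sign-aligned so each
#' map's skewness is positive.
#'
#' @param datasets list of `subject_dataset` objects or T x V matrices, all
#'   sharing the same voxel dimension.
#' @param G1 subject-level PCA order.
#' @param G2 group-level PCA/ICA order; must satisfy `G2 <= G1`.
#' @param seed integer seed.
#' @return object of class `group_ica_result`: `group_maps` (G2 x V,
#'   z-scored), `group_mixing` (M*G1 x G2), `infomax` diagnostics.
#' @export
group_ica <- function(datasets, G1, G2, seed = 1L) {
  if (G2 > G1) stop("G2 must not exceed G1")
  mats <- lapply(datasets, function(d) if (is.list(d)) d$data else d)
  Vs <- vapply(mats, ncol, integer(1))
  if (length(unique(Vs)) != 1) {
    stop("all datasets must share the same voxel dimension")
  }
  reduced <- lapply(mats, function(m) pca_reduce(m, G1)$reduced)
  concat <- do.call(rbind, reduced)
  gw <- whiten_rows(concat, G2)
  fit <- infomax(gw$X, seed = seed)
  maps <- fit$unmixing %*% gw$X
  mixing <- gw$back %*% solve(fit$unmixing)
  maps <- zscore(maps)
  fl <- skew_flip(maps, mixing)
  structure(list(group_maps = fl$maps, group_mixing = fl$mixing,
                 infomax = fit, G1 = G1, G2 = G2),
            class = "group_ica_result")
}
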