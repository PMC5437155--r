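#' Functional network connectivity (FNC) matrix
#'
#' Pearson correlation matrix among the time courses of N networks.
#'
#' @param tcs matrix (T x N) of network time courses, non-constant columns.
#' @return symmetric N x N correlation matrix with unit diagonal.
#' @export
fnc <- function(tcs) {
  stopifnot(ncol(tcs) >= 2)
  sds <- apply(tcs, 2, sd)
  if (any(sds == 0)) {
    stop("constant time course for network ", which(sds == 0)[1])
  }
  cor(tcs)
}

# generalized (signed) modularity matrix: positive and negative null models
# weighted by their strength fractions (asymmetric signed extension).
signed_modularity_matrix <- function(W) {
  W <- as.matrix(W)
  diag(W) <- 0
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  sp <- rowSums(Wp); sn <- rowSums(Wn)
  vp <- sum(sp); vn <- sum(sn)
  B <- matrix(0, nrow(W), ncol(W))
  if (vp > 0) B <- B + (Wp - outer(sp, sp) / vp) / vp
  if (vn > 0) B <- B - (Wn - outer(sn, sn) / vn) / (vp + vn)
  B
}

#' Modularity Q of a partition on a signed weighted network
#'
#' Evaluates the signed-modularity quality of `partition` on `W`: the
#' positive-weight modularity minus the negative-weight null contribution
#' down-weighted by the negative strength fraction (the standard asymmetric
#' signed extension). For non-negative `W` this reduces to classic
#' Newman-Girvan Q. The diagonal (self-connectivity) is ignored.
#'
#' @param W symmetric matrix; negative entries permitted.
#' @param partition integer community label per node.
#' @return scalar Q.
#' @export
modularity_q <- function(W, partition) {
  B <- signed_modularity_matrix(W)
  same <- outer(partition, partition, `==`)
  sum(B[same])
}

#' Community detection by the leading-eigenvector method
#'
#' Newman's spectral bisection on the (signed) modularity matrix with
#' single-node fine-tuning, applied recursively while a split still increases
#' Q. Deterministic: no randomness is involved.
#'
#' @param W symmetric connectivity matrix; negative entries permitted.
#' @return list with `partition` (integer labels, contiguous from 1) and `Q`.
#' @export
modularity_partition <- function(W) {
  W <- as.matrix(W)
  stopifnot(isSymmetric(unname(W), tol = 1e-10))
  n <- nrow(W)
  B <- signed_modularity_matrix(W)
  if (all(B == 0)) {
    return(list(partition = rep(1L, n), Q = 0))
  }
  labels <- rep(1L, n)
  next_label <- 2L
  queue <- list(seq_len(n))
  while (length(queue) > 0) {
    g <- queue[[1]]; queue <- queue[-1]
    if (length(g) < 2) next
    Bg <- B[g, g, drop = FALSE]
    # splitting g into s = +1 / -1 changes Q by (s' Bg s - 1' Bg 1)
    eg <- eigen(Bg, symmetric = TRUE)
    s <- ifelse(eg$vectors[, 1] >= 0, 1, -1)
    # fine-tuning: greedy single-node flips while they increase s' Bg s
    repeat {
      gains <- -2 * s * as.vector(Bg %*% s) + 2 * diag(Bg) * s * s
      best <- which.max(gains)
      if (gains[best] <= 1e-12) break
      s[best] <- -s[best]
    }
    dq <- as.numeric(t(s) %*% Bg %*% s - sum(Bg))
    if (dq > 1e-12 && any(s > 0) && any(s < 0)) {
      g1 <- g[s > 0]; g2 <- g[s < 0]
      labels[g2] <- next_label
      next_label <- next_label + 1L
      queue <- c(queue, list(g1), list(g2))
    }
  }
  labels <- as.integer(factor(labels, levels = unique(labels)))
  list(partition = labels, Q = modularity_q(W, labels))
}

#' Adjusted mutual information between two partitions
#'
#' Mutual information corrected for chance under the permutation
#' (hypergeometric) model and normalized by the maximum of the two
#' entropies: identical partitions (up to relabeling) score 1, independent
#' random partitions score ~0.
#'
#' @param p,q integer label vectors of the same length.
#' @return scalar AMI.
#' @export
ami <- function(p, q) {
  if (length(p) != length(q)) stop("partitions must have the same length")
  N <- length(p)
  tab <- table(p, q)
  a <- rowSums(tab); b <- colSums(tab)
  # identical up to relabeling: one nonzero cell per row and per column
  # (handled up front: for small all-singleton partitions the chance
  # correction can equal the entropy, degenerating the normalization)
  if (nrow(tab) == ncol(tab) &&
      all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)) {
    return(1)
  }
  # mutual information
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + nij / N * log(N * nij / (a[i] * b[j]))
  }
  hp <- -sum(a / N * log(a / N))
  hq <- -sum(b / N * log(b / N))
  if (max(hp, hq) == 0) return(1)
  # expected MI under the permutation model
  emi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    ai <- a[i]; bj <- b[j]
    lo <- max(1, ai + bj - N); hi <- min(ai, bj)
    if (lo > hi) next
    nij <- lo:hi
    lw <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(N - ai + 1) +
      lgamma(N - bj + 1) - lgamma(N + 1) - lgamma(nij + 1) -
      lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
      lgamma(N - ai - bj + nij + 1)
    emi <- emi + sum(nij / N * log(N * nij / (ai * bj)) * exp(lw))
  }
  denom <- max(hp, hq) - emi
  if (abs(denom) < 1e-15) return(0)
  as.numeric((mi - emi) / denom)
}

#' Threshold a connectivity matrix to a target sparsity
#'
#' Takes absolute values, zeroes the diagonal, and keeps the top
#' `sparsity * E` off-diagonal pairs by magnitude (E = number of unique
#' pairs), zeroing the rest. Ties at the cutoff are all kept.
#'
#' @param W symmetric matrix.
#' @param sparsity fraction of pairs to preserve, in (0, 1].
#' @return symmetric non-negative matrix with zero diagonal.
#' @export
threshold_sparsity <- function(W, sparsity = 0.5) {
  stopifnot(sparsity > 0, sparsity <= 1)
  A <- abs(as.matrix(W))
  diag(A) <- 0
  up <- upper.tri(A)
  vals <- A[up]
  k <- ceiling(sparsity * length(vals))
  cut <- sort(vals, decreasing = TRUE)[k]
  A[A < cut] <- 0
  A
}

#' Weighted graph metrics of a thresholded connectivity matrix
#'
#' Node-averaged weighted metrics in the brain-connectivity convention,
#' assuming weights in \[0, 1\] (e.g. from [threshold_sparsity()]):
#' strength = row sums; clustering = geometric-mean triangle formula;
#' global/local efficiency from shortest paths on length = 1/weight
#' (unreachable pairs contribute zero efficiency).
#'
#' @param W non-negative symmetric matrix, zero diagonal.
#' @return list with `node_strength`, `clustering`, `global_eff`,
#'   `local_eff` (each the average over nodes).
#' @export
graph_metrics <- function(W) {
  W <- as.matrix(W)
  stopifnot(all(W >= 0))
  diag(W) <- 0
  n <- nrow(W)
  strength <- mean(rowSums(W))
  # weighted clustering coefficient (geometric mean of triangle weights)
  cr <- W^(1 / 3)
  tri <- diag(cr %*% cr %*% cr)
  deg <- rowSums(W > 0)
  clust <- ifelse(deg >= 2, tri / (deg * (deg - 1)), 0)
  # efficiencies on lengths 1/w
  einv <- function(A) {
    if (nrow(A) < 2 || all(A == 0)) {
      return(matrix(0, nrow(A), nrow(A)))
    }
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    e <- 1 / d
    e[!is.finite(e)] <- 0
    diag(e) <- 0
    e
  }
  E <- einv(W)
  global_eff <- sum(E) / (n * (n - 1))
  local_eff <- vapply(seq_len(n), function(u) {
    nb <- which(W[u, ] > 0)
    if (length(nb) < 2) return(0)
    e_nb <- einv(W[nb, nb, drop = FALSE])
    sw <- W[u, nb]^(1 / 3)
    num <- sum(outer(sw, sw) * e_nb^(1 / 3))
    k <- length(nb)
    num / (k * (k - 1))
  }, numeric(1))
  list(node_strength = strength, clustering = mean(clust),
       global_eff = global_eff, local_eff = mean(local_eff))
}

#' Build an FNC graph with partition, Q, and graph metrics
#'
#' Convenience wrapper: computes the FNC matrix from time courses (or takes
#' one directly), detects communities on the signed matrix, and computes
#' weighted graph metrics on the absolute matrix thresholded to `sparsity`.
#'
#' @param x T x N time-course matrix, or an N x N symmetric FNC matrix.
#' @param sparsity sparsity used for the graph metrics (default 0.5).
#' @return object of class `fnc_graph`: `fnc`, `partition`, `Q`, `metrics`.
#' @export
fnc_graph <- function(x, sparsity = 0.5) {
  Wm <- if (isSymmetric(unname(as.matrix(x)), tol = 1e-10) &&
            nrow(x) == ncol(x)) as.matrix(x) else fnc(x)
  mp <- modularity_partition(Wm)
  metrics <- graph_metrics(threshold_sparsity(Wm, sparsity))
  structure(list(fnc = Wm, partition = mp$partition, Q = mp$Q,
                 metrics = metrics, sparsity = sparsity),
            class = "fnc_graph")
}
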