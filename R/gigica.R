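#' Negentropy of a standardized signal
#'
#' Approximates negentropy with the log-cosh contrast,
#' `J(y) = (E G(y) - E G(nu))^2`, `G(u) = log cosh(u)`, where `nu` is a
#' standard Gaussian. `E G(nu)` is an analytic constant (~0.37457) computed
#' once by quadrature; a Monte-Carlo reference can be requested instead via
#' `n_gauss_samples`.
#'
#' @param y numeric vector, standardized (zero mean, unit variance).
#' @param n_gauss_samples optional count; if given, `E G(nu)` is estimated
#'   from that many seeded Gaussian samples instead of the analytic constant.
#' @param seed integer seed for the Monte-Carlo reference.
#' @return non-negative scalar.
#' @export
negentropy <- function(y, n_gauss_samples = NULL, seed = 1L) {
  if (sd(y) == 0) stop("negentropy undefined for zero-variance input")
  ref <- if (is.null(n_gauss_samples)) {
    gauss_logcosh_const()
  } else {
    with_seed(seed, mean(logcosh(rnorm(n_gauss_samples))))
  }
  (mean(logcosh(y)) - ref)^2
}

# numerically safe log(cosh(u))
logcosh <- function(u) {
  a <- abs(u)
  a + log1p(exp(-2 * a)) - log(2)
}

#' Estimate one subject's components guided by group-level maps
#'
#' For each group-level (reference) map, in order, a demixing vector `w` on
#' the unit sphere of the subject's whitened space maximizes
#' `F(w) = lambda * J(y) + (1 - lambda) * corr(y, reference)` with
#' `y = w' X`, where `J` is the log-cosh negentropy. Optimization is
#' projected gradient ascent with step halving; deflation keeps each `w`
#' orthogonal to the previously accepted vectors, so a subject's components
#' are mutually uncorrelated. `w` is initialized from the projection of the
#' reference onto the whitened space, which ties each subject component to
#' its reference (built-in correspondence and sign alignment).
#'
#' @param subject_data `subject_dataset` or T x V matrix.
#' @param group_maps matrix (n_ref x V) of z-scored reference maps.
#' @param seed integer seed (kept for interface symmetry; the ascent is
#'   deterministic given the data and references).
#' @param lambda weight of the negentropy (independence) term versus the
#'   correspondence term, in \[0, 1\]; default 0.5.
#' @param tol convergence tolerance on the objective increase.
#' @param max_iter maximum ascent iterations per component.
#' @param corr_floor components whose final correlation with the reference
#'   falls below this value are flagged (still returned).
#' @return object of class `subject_ic_set`: `maps` (n_ref x V, z-scored, in
#'   reference order), `tcs` (T x n_ref), `objective_trace` (list of
#'   per-iteration objective values, non-decreasing), `ref_corr`, `flagged`.
#' @export
estimate_subject_ics <- function(subject_data, group_maps, seed = 1L,
                                 lambda = 0.5, tol = 1e-7, max_iter = 1000L,
                                 corr_floor = 0.2) {
  data <- if (is.list(subject_data)) subject_data$data else subject_data
  k <- nrow(group_maps)
  wh <- whiten_rows(data, k)
  V <- ncol(wh$X)
  # standardize references in the population convention so corr(y, r) = w.rho
  mu <- rowMeans(group_maps)
  s <- sqrt(rowMeans(group_maps^2) - mu^2)
  R <- (group_maps - mu) / s
  fit <- cpp_gigica_subject(wh$X, R, lambda, gauss_logcosh_const(),
                            tol, as.integer(max_iter), 0.2, corr_floor)
  maps <- zscore(fit$Y)
  tcs <- estimate_tcs(data, maps)
  structure(list(maps = maps, tcs = tcs, objective_trace = fit$traces,
                 ref_corr = as.numeric(fit$ref_corr),
                 flagged = as.logical(fit$flagged),
                 demixing = fit$W, lambda = lambda),
            class = "subject_ic_set")
}

#' Estimate subject time courses from spatial maps
#'
#' Least-squares solution of `data ~ tcs %*% maps` after removing each
#' voxel's temporal mean: `tcs = data_c %*% t(maps) %*% solve(maps %*%
#' t(maps))` (the right pseudo-inverse of the maps).
#'
#' @param subject_data `subject_dataset` or T x V matrix.
#' @param maps matrix (k x V) of z-scored maps with full row rank.
#' @return matrix (T x k) of time courses.
#' @export
estimate_tcs <- function(subject_data, maps) {
  data <- if (is.list(subject_data)) subject_data$data else subject_data
  G <- tcrossprod(maps)
  if (rcond(G) < 1e-12) {
    cc <- abs(cor(t(maps)))
    diag(cc) <- 0
    worst <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    stop("maps are rank deficient; most collinear pair: components ",
         worst[1], " and ", worst[2])
  }
  dc <- sweep(data, 2, colMeans(data))
  dc %*% t(maps) %*% solve(G)
}

#' GIG-ICA: group information guided ICA for multiple subjects
#'
#' Runs temporal-concatenation group ICA (`G1 = G2 = n_components`) and then
#' refines each subject's components with [estimate_subject_ics()], the
#' reference-guided negentropy-plus-correspondence ascent. All components are
#' computed (no artifact removal), and subject components are ordered
#' identically to the group maps.
#'
#' @param datasets list of `subject_dataset` objects or T x V matrices.
#' @param n_components model order (G1 = G2).
#' @param seed integer seed.
#' @param lambda independence-versus-correspondence weight; see
#'   [estimate_subject_ics()].
#' @return object of class `decomposition_result` with fields `method`
#'   ("gigica"), `model_order`, `group_maps`, `subject_maps` (list of
#'   z-scored n x V matrices), `subject_tcs` (list of T x n matrices),
#'   `subject_ics` (full per-subject diagnostics).
#' @export
gigica <- function(datasets, n_components, seed = 1L, lambda = 0.5) {
  g <- group_ica(datasets, G1 = n_components, G2 = n_components, seed = seed)
  ics <- lapply(datasets, estimate_subject_ics, group_maps = g$group_maps,
                seed = seed, lambda = lambda)
  structure(list(
    method = "gigica", model_order = n_components,
    group_maps = g$group_maps,
    subject_maps = lapply(ics, `[[`, "maps"),
    subject_tcs = lapply(ics, `[[`, "tcs"),
    subject_ics = ics, group_ica = g
  ), class = "decomposition_result")
}
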