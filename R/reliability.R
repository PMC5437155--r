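#' Voxelwise one-sample t map with an FDR-corrected mask
#'
#' Right-tailed one-sample t-test against zero at each voxel across datasets,
#' with Benjamini-Hochberg control of the false discovery rate at level `q`.
#' Zero-variance voxels get p = 1.
#'
#' @param maps matrix (n_datasets x V); rows are datasets, columns voxels.
#' @param q FDR level (the conventional network-map threshold is p < 0.01
#'   FDR-corrected, i.e. `q = 0.01`).
#' @return list with `t_map` (length V), `p` (right-tailed p-values),
#'   `mask` (logical; BH-adjusted p <= q).
#' @export
one_sample_t_fdr <- function(maps, q = 0.01) {
  n <- nrow(maps)
  stopifnot(n >= 2)
  mu <- colMeans(maps)
  s <- sqrt(colSums((maps - rep(mu, each = n))^2) / (n - 1))
  tstat <- ifelse(s > 0, mu / (s / sqrt(n)), 0)
  p <- ifelse(s > 0, pt(tstat, df = n - 1, lower.tail = FALSE), 1)
  padj <- p.adjust(p, method = "BH")
  list(t_map = tstat, p = p, mask = padj <= q)
}

#' One-way ANOVA intraclass correlation coefficient
#'
#' Treats subjects as groups with k = 2 observations each (e.g. scan 2 and
#' scan 3 of the same subject) and computes
#' `ICC = sigma_p^2 / (sigma_p^2 + sigma_e^2)` with
#' `sigma_p^2 = max(0, (MSB - MSW) / 2)` (inter-subject variance) and
#' `sigma_e^2 = MSW` (error variance). Negative variance components are
#' clamped to zero, so the ICC lies in \[0, 1\]; it is 0 when both variance
#' components vanish.
#'
#' @param x1,x2 paired observations, length n >= 2.
#' @return object of class `icc_result`: `icc`, `sigma_p2`, `sigma_e2`.
#' @export
icc_oneway <- function(x1, x2) {
  n <- length(x1)
  if (n < 2 || length(x2) != n) stop("need n >= 2 paired observations")
  subj_mean <- (x1 + x2) / 2
  grand <- mean(c(x1, x2))
  msb <- 2 * sum((subj_mean - grand)^2) / (n - 1)
  msw <- sum((x1 - subj_mean)^2 + (x2 - subj_mean)^2) / n
  sigma_p2 <- max(0, (msb - msw) / 2)
  sigma_e2 <- msw
  icc <- if (sigma_p2 + sigma_e2 == 0) 0 else sigma_p2 / (sigma_p2 + sigma_e2)
  structure(list(icc = icc, sigma_p2 = sigma_p2, sigma_e2 = sigma_e2),
            class = "icc_result")
}

# vectorized one-way ICC over the columns of two n x E matrices
icc_oneway_cols <- function(A, B) {
  n <- nrow(A)
  subj_mean <- (A + B) / 2
  grand <- colMeans(rbind(A, B))
  msb <- 2 * colSums((subj_mean - rep(grand, each = n))^2) / (n - 1)
  msw <- colSums((A - subj_mean)^2 + (B - subj_mean)^2) / n
  sp <- pmax(0, (msb - msw) / 2)
  tot <- sp + msw
  ifelse(tot == 0, 0, sp / tot)
}

#' Test-retest reliability of a network map
#'
#' Voxelwise one-way ICC inside a mask, averaged over mask voxels.
#' Short-term reliability compares scan 2 with scan 3; long-term compares
#' scan 1 with the average of scans 2 and 3.
#'
#' @param maps_by_scan list of three matrices (subjects x V), one per scan,
#'   rows aligned by subject.
#' @param mask logical vector of length V, non-empty.
#' @param mode "short" or "long".
#' @return mean ICC over mask voxels.
#' @export
network_reliability <- function(maps_by_scan, mask,
                                mode = c("short", "long")) {
  mode <- match.arg(mode)
  if (!any(mask)) stop("empty mask")
  stopifnot(length(maps_by_scan) == 3)
  if (mode == "short") {
    A <- maps_by_scan[[2]][, mask, drop = FALSE]
    B <- maps_by_scan[[3]][, mask, drop = FALSE]
  } else {
    A <- maps_by_scan[[1]][, mask, drop = FALSE]
    B <- (maps_by_scan[[2]] + maps_by_scan[[3]])[, mask, drop = FALSE] / 2
  }
  mean(icc_oneway_cols(A, B))
}

#' Test-retest reliability of functional network connectivity
#'
#' One-way ICC of each connectivity element (unique network pair) across
#' subjects, between scans.
#'
#' @param fnc_by_scan list of three matrices (subjects x E), one per scan;
#'   E is the number of unique network pairs.
#' @param mode "short" (scan 2 vs scan 3) or "long" (scan 1 vs the scan 2/3
#'   average).
#' @return numeric vector of length E of ICC values.
#' @export
connectivity_icc <- function(fnc_by_scan, mode = c("short", "long")) {
  mode <- match.arg(mode)
  stopifnot(length(fnc_by_scan) == 3)
  if (mode == "short") {
    icc_oneway_cols(fnc_by_scan[[2]], fnc_by_scan[[3]])
  } else {
    icc_oneway_cols(fnc_by_scan[[1]],
                    (fnc_by_scan[[2]] + fnc_by_scan[[3]]) / 2)
  }
}
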