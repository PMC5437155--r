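#' @useDynLib gigiva, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor pt qt rnorm runif sd t.test p.adjust var integrate
#' @importFrom utils write.csv
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls never perturb user-level streams.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Z-score a vector or the rows of a matrix
#'
#' Centers to zero mean and scales to unit standard deviation (sample SD,
#' denominator `n - 1`). For matrices each row is standardized independently;
#' this is the convention used for component spatial maps, where rows are
#' components and columns voxels.
#'
#' @param x numeric vector or matrix.
#' @return object of the same shape, standardized.
#' @export
zscore <- function(x) {
  if (is.matrix(x)) {
    mu <- rowMeans(x)
    s <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
    if (any(s == 0)) stop("cannot z-score a constant row")
    (x - mu) / s
  } else {
    s <- sd(x)
    if (s == 0) stop("cannot z-score a constant vector")
    (x - mean(x)) / s
  }
}

# absolute-correlation matrix between rows of A (n_a x V) and rows of B (n_b x V)
abs_cor_rows <- function(A, B) {
  abs(cor(t(A), t(B)))
}

# E[log cosh(Z)] for Z ~ N(0,1); computed once by quadrature and cached.
gauss_logcosh_const <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- integrate(function(u) logcosh(u) * exp(-u^2 / 2) / sqrt(2 * pi),
                        -Inf, Inf, rel.tol = 1e-12)$value
    }
    val
  }
})
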