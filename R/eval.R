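#' Greedy matching between estimated components and templates
#'
#' Repeatedly selects the globally largest remaining similarity, records the
#' pair, and deletes its row and column, until one side is exhausted. Ties
#' are broken by the smallest (row, column) index. Note this greedy rule can
#' differ from the optimal assignment: it maximizes each pick locally, not
#' the total similarity.
#'
#' @param similarity matrix (n_estimated x n_templates) of absolute
#'   correlations.
#' @return object of class `match_table`: `pairs` (data.frame with columns
#'   `est`, `template`, `similarity`), `unmatched_est`, `unmatched_template`.
#' @export
greedy_match <- function(similarity) {
  similarity <- as.matrix(similarity)
  nr <- nrow(similarity); nc <- ncol(similarity)
  rows <- seq_len(nr); cols <- seq_len(nc)
  pairs <- data.frame(est = integer(), template = integer(),
                      similarity = numeric())
  while (length(rows) > 0 && length(cols) > 0) {
    sub <- similarity[rows, cols, drop = FALSE]
    best <- max(sub)
    hit <- which(sub == best, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    pairs <- rbind(pairs, data.frame(est = rows[hit[1]],
                                     template = cols[hit[2]],
                                     similarity = best))
    rows <- rows[-hit[1]]
    cols <- cols[-hit[2]]
  }
  structure(list(pairs = pairs, unmatched_est = rows,
                 unmatched_template = cols),
            class = "match_table")
}

#' Accuracy of an estimate against ground truth
#'
#' Absolute Pearson correlation between an estimated component (or time
#' course) and its matched ground-truth counterpart.
#'
#' @param estimated,truth numeric vectors of equal length, non-constant.
#' @return scalar in \[0, 1\].
#' @export
accuracy <- function(estimated, truth) {
  stopifnot(length(estimated) == length(truth))
  if (sd(estimated) == 0 || sd(truth) == 0) {
    stop("accuracy undefined for constant input")
  }
  abs(cor(estimated, truth))
}

#' Two-tailed paired t-test
#'
#' @param a,b numeric vectors of equal length n >= 2 with non-constant
#'   differences.
#' @return list with `t`, `p` (two-tailed), `df`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (sd(a - b) == 0) stop("paired t-test undefined: zero-variance differences")
  ht <- t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Bonferroni significance flags
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param alpha family-wise level.
#' @return logical vector: `p < alpha / length(pvals)`.
#' @export
bonferroni <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0) return(logical(0))
  pvals < alpha / length(pvals)
}

# Mean ground-truth map across subjects for each source common to ALL
# subjects (sources are aligned by index). Sources present in only a subset
# of subjects (varied source counts) or subject-unique sources are not
# templates; estimates matching them are left unmatched.
build_templates <- function(truth) {
  n_src <- min(vapply(truth, function(g) sum(g$labels == "common"),
                      integer(1)))
  V <- ncol(truth[[1]]$maps)
  templates <- matrix(0, n_src, V)
  for (j in seq_len(n_src)) {
    templates[j, ] <- Reduce(`+`, lapply(truth, function(g) g$maps[j, ])) /
      length(truth)
  }
  templates
}

# Score one method's decomposition against ground truth: match group-level
# maps to the mean-GT templates, propagate the matching to subjects, and
# compute per-subject/component absolute-correlation accuracy tables.
score_decomposition <- function(result, truth) {
  templates <- build_templates(truth)
  sim <- abs_cor_rows(result$group_maps, templates)
  mt <- greedy_match(sim)
  M <- length(truth)
  n_templ <- nrow(templates)
  has_unique <- any(vapply(truth, function(g) any(g$labels == "unique"),
                           logical(1)))
  cols <- n_templ + as.integer(has_unique && length(mt$unmatched_est) == 1)
  spatial <- matrix(NA_real_, M, cols)
  temporal <- matrix(NA_real_, M, cols)
  for (p in seq_len(nrow(mt$pairs))) {
    i <- mt$pairs$est[p]; j <- mt$pairs$template[p]
    for (m in seq_len(M)) {
      if (j <= nrow(truth[[m]]$maps) && truth[[m]]$labels[j] == "common") {
        spatial[m, j] <- accuracy(result$subject_maps[[m]][i, ],
                                  truth[[m]]$maps[j, ])
        temporal[m, j] <- accuracy(result$subject_tcs[[m]][, i],
                                   truth[[m]]$tcs[, j])
      }
    }
  }
  if (has_unique && length(mt$unmatched_est) == 1) {
    u <- mt$unmatched_est[1]
    for (m in seq_len(M)) {
      uj <- which(truth[[m]]$labels == "unique")
      if (length(uj) == 1) {
        spatial[m, cols] <- accuracy(result$subject_maps[[m]][u, ],
                                     truth[[m]]$maps[uj, ])
        temporal[m, cols] <- accuracy(result$subject_tcs[[m]][, u],
                                      truth[[m]]$tcs[, uj])
      }
    }
  }
  structure(list(
    spatial = spatial, temporal = temporal, match = mt,
    subject_mean_spatial = rowMeans(spatial, na.rm = TRUE),
    subject_mean_temporal = rowMeans(temporal, na.rm = TRUE)
  ), class = "accuracy_table")
}

#' Score two methods' decompositions of the same datasets
#'
#' Builds mean ground-truth templates, matches each method's group-level
#' maps to them with the greedy rule, propagates the matching to the subject
#' maps and time courses, and compares the two methods with two-tailed paired
#' t-tests — on per-subject mean accuracy (`by = "subject"`, the usual mode)
#' or per component across subjects (`by = "component"`, used when a
#' subject-unique source is present).
#'
#' @param results named list of exactly two `decomposition_result` objects
#'   computed on identical datasets; t statistics are first minus second.
#' @param truth list of `ground_truth` objects.
#' @param by "subject" or "component".
#' @return list with per-method `accuracy_table`s (`tables`) and a data.frame
#'   `tests` of paired t-tests (spatial and temporal).
#' @export
score_experiment <- function(results, truth, by = c("subject", "component")) {
  by <- match.arg(by)
  stopifnot(length(results) == 2)
  tables <- lapply(results, score_decomposition, truth = truth)
  nm <- names(results)
  tests <- NULL
  run_test <- function(a, b) {
    out <- tryCatch(paired_ttest(a[stats::complete.cases(a, b)],
                                 b[stats::complete.cases(a, b)]),
                    error = function(e) list(t = 0, p = 1, df = NA_real_))
    out
  }
  if (by == "subject") {
    for (dom in c("spatial", "temporal")) {
      a <- tables[[1]][[paste0("subject_mean_", dom)]]
      b <- tables[[2]][[paste0("subject_mean_", dom)]]
      tt <- run_test(a, b)
      tests <- rbind(tests, data.frame(
        domain = dom, component = NA_integer_,
        t = tt$t, p = tt$p, df = tt$df))
    }
  } else {
    for (dom in c("spatial", "temporal")) {
      A <- tables[[1]][[dom]]; B <- tables[[2]][[dom]]
      for (j in seq_len(ncol(A))) {
        tt <- run_test(A[, j], B[, j])
        tests <- rbind(tests, data.frame(
          domain = dom, component = j, t = tt$t, p = tt$p, df = tt$df))
      }
    }
  }
  tests$comparison <- paste(nm[1], "-", nm[2])
  list(tables = tables, tests = tests)
}
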