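#' Run both decomposition methods on one simulated setting and score them
#'
#' Generates a preset dataset, runs IVA-GL and GIG-ICA with the same model
#' order, and scores both against the ground truth. The paired t statistics
#' are IVA minus GIG-ICA.
#'
#' @param preset simulation preset name (see [generate_experiment()]).
#' @param seed integer seed; data generation and both decompositions are
#'   deterministic given it.
#' @param n_components model order (G1 = G2 = I1); defaults to the maximum
#'   number of true sources.
#' @param cnr,n_timepoints forwarded to [generate_experiment()].
#' @param by scoring mode, "subject" or "component" (see
#'   [score_experiment()]).
#' @param lambda GIG-ICA independence weight.
#' @return list with `score` (see [score_experiment()]), `results` (the two
#'   `decomposition_result`s), `truth`, and `setting` metadata.
#' @export
run_sim_setting <- function(preset, seed = 1L, n_components = NULL, cnr = 2,
                            n_timepoints = 150,
                            by = c("subject", "component"), lambda = 0.5) {
  by <- match.arg(by)
  gen <- generate_experiment(preset, seed = seed, cnr = cnr,
                             n_timepoints = n_timepoints)
  if (is.null(n_components)) {
    n_components <- max(vapply(gen$truth, function(g) nrow(g$maps),
                               integer(1)))
  }
  res_iva <- iva_gl(gen$datasets, I1 = n_components, seed = seed + 1L)
  res_gig <- gigica(gen$datasets, n_components = n_components,
                    seed = seed + 2L, lambda = lambda)
  sc <- score_experiment(list(iva = res_iva, gigica = res_gig), gen$truth,
                         by = by)
  list(score = sc, results = list(iva = res_iva, gigica = res_gig),
       truth = gen$truth,
       setting = list(preset = preset, seed = seed,
                      n_components = n_components, cnr = cnr,
                      n_timepoints = n_timepoints))
}

#' Run a full simulation experiment sweep
#'
#' Sweeps the settings of one simulation experiment (CNR levels, numbers of
#' time points, or model orders), runs both methods at each setting, and
#' collects per-subject accuracy rows plus per-setting paired t-tests with
#' Bonferroni flags across the sweep. With `outdir` set, writes
#' `accuracy.csv` and `ttests.csv`; reruns with the same seed produce
#' byte-identical files.
#'
#' @param preset preset name.
#' @param seed base integer seed; setting i uses `seed + 1000 * i`.
#' @param cnr_values CNR sweep for exp1_quality (default 0.5 to 2 by 0.1).
#' @param timepoint_values time-point sweep for exp1_quantity (default 40 to
#'   120 by 20).
#' @param model_orders model orders; default depends on the preset
#'   (exp2_varied_sources: 7 and 8; exp2_model_order: 6, 8, 10).
#' @param outdir optional output directory for CSV tables.
#' @param lambda GIG-ICA independence weight.
#' @return list of data.frames `accuracy` (setting, method, subject, mean
#'   spatial/temporal accuracy) and `ttests` (setting, domain, t, p, df,
#'   Bonferroni flag at family level 0.05 across the sweep).
#' @export
run_simulation_experiment <- function(preset, seed = 1L,
                                      cnr_values = seq(0.5, 2, by = 0.1),
                                      timepoint_values = seq(40, 120, by = 20),
                                      model_orders = NULL,
                                      outdir = NULL, lambda = 0.5) {
  settings <- switch(preset,
    exp1_quality = lapply(cnr_values, function(x) list(cnr = x)),
    exp1_quantity = lapply(timepoint_values, function(x) list(T_len = x)),
    exp2_varied_sources = lapply(model_orders %||% c(7L, 8L),
                                 function(x) list(order = x)),
    exp2_model_order = lapply(model_orders %||% c(6L, 8L, 10L),
                              function(x) list(order = x)),
    exp3_unique = list(list(order = 8L)),
    stop("unknown preset '", preset, "'")
  )
  by <- if (preset == "exp3_unique") "component" else "subject"
  acc <- NULL; tts <- NULL
  for (i in seq_along(settings)) {
    s <- settings[[i]]
    run <- run_sim_setting(
      preset, seed = seed + 1000L * i,
      n_components = s$order,
      cnr = s$cnr %||% 2, n_timepoints = s$T_len %||% 150,
      by = by, lambda = lambda
    )
    lab <- paste0(
      if (!is.null(s$cnr)) paste0("cnr=", s$cnr),
      if (!is.null(s$T_len)) paste0("T=", s$T_len),
      if (!is.null(s$order)) paste0("order=", s$order)
    )
    for (method in names(run$score$tables)) {
      tb <- run$score$tables[[method]]
      acc <- rbind(acc, data.frame(
        setting = lab, method = method,
        subject = seq_along(tb$subject_mean_spatial),
        spatial = tb$subject_mean_spatial,
        temporal = tb$subject_mean_temporal
      ))
    }
    tt <- run$score$tests
    tt$setting <- lab
    tts <- rbind(tts, tt)
  }
  tts$bonferroni <- FALSE
  for (dom in unique(tts$domain)) {
    sel <- tts$domain == dom
    tts$bonferroni[sel] <- bonferroni(tts$p[sel], 0.05)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.csv(acc, file.path(outdir, "accuracy.csv"), row.names = FALSE)
    write.csv(tts, file.path(outdir, "ttests.csv"), row.names = FALSE)
  }
  list(accuracy = acc, ttests = tts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Match components between two methods by group-level maps
#'
#' Greedy matching on the absolute correlation between the two methods'
#' group-level component maps; pairs below `threshold` are discarded (the
#' conventional cut for "the same network seen by both methods" is 0.5).
#'
#' @param res_a,res_b `decomposition_result` objects with equal model order.
#' @param threshold minimum absolute correlation for a retained pair.
#' @return `match_table` whose `pairs` all meet the threshold.
#' @export
cross_method_match <- function(res_a, res_b, threshold = 0.5) {
  stopifnot(res_a$model_order == res_b$model_order)
  mt <- greedy_match(abs_cor_rows(res_a$group_maps, res_b$group_maps))
  drop <- mt$pairs$similarity < threshold
  mt$unmatched_est <- sort(c(mt$unmatched_est, mt$pairs$est[drop]))
  mt$unmatched_template <- sort(c(mt$unmatched_template,
                                  mt$pairs$template[drop]))
  mt$pairs <- mt$pairs[!drop, , drop = FALSE]
  mt
}

# read a 4D NIfTI file into a T x V matrix (voxels in array order)
read_nifti_tv <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the real-data mode requires the RNifti package")
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  stopifnot(length(d) == 4)
  t(matrix(as.vector(img), prod(d[1:3]), d[4]))
}

#' Test-retest reliability and FNC study on real (or file-based) data
#'
#' Runs both methods on every dataset-as-file, matches their components at
#' the group level (|r| > `threshold`), restricts to a user-supplied list of
#' meaningful matched networks, and computes: per-network one-sample t maps
#' with FDR masks (joint mask = intersection of both methods' masks),
#' short/long-term network reliability (one-way ICC), per-dataset FNC with
#' modularity Q, AMI-based modularity reliability (mean AMI over all
#' cross-scan dataset pairs, or subject-matched pairs), connectivity ICC, and
#' weighted graph metrics at the given sparsity.
#'
#' @param files character vector of 4D NIfTI paths, one per dataset, or a
#'   list of T x V matrices.
#' @param scan integer scan-session label (1, 2, or 3) per dataset.
#' @param subject subject identifier per dataset.
#' @param n_components model order for both methods.
#' @param keep_list indices into the matched-pair list selecting the
#'   meaningful networks (artifact screening is manual by design).
#' @param seed integer seed.
#' @param threshold cross-method matching threshold.
#' @param q FDR level for the one-sample t masks.
#' @param sparsity sparsity for the graph metrics.
#' @param ami_pairing "all" (every cross-scan dataset pair) or "matched"
#'   (same-subject pairs only).
#' @param outdir optional directory for CSV tables.
#' @return list of data.frames: `reliability` (per network and method, short
#'   and long-term mean ICC), `modularity` (per method: mean-FNC Q, mean
#'   individual Q, AMI short/long), `connectivity_icc`, `graph_metrics`.
#' @export
run_realdata_study <- function(files, scan, subject, n_components, keep_list,
                               seed = 1L, threshold = 0.5, q = 0.01,
                               sparsity = 0.5,
                               ami_pairing = c("all", "matched"),
                               outdir = NULL) {
  ami_pairing <- match.arg(ami_pairing)
  if (length(scan) != length(files) || length(subject) != length(files)) {
    stop("need one scan label and one subject id per dataset")
  }
  if (!all(sort(unique(scan)) == 1:3)) stop("scan labels must cover 1, 2, 3")
  mats <- if (is.character(files)) lapply(files, read_nifti_tv) else files
  # analysis mask: voxels with nonzero temporal variance in every dataset
  nz <- Reduce(`&`, lapply(mats, function(m) {
    apply(m, 2, function(v) var(v) > 0)
  }))
  if (!any(nz)) stop("no voxel has nonzero variance in all datasets")
  mats <- lapply(mats, function(m) m[, nz, drop = FALSE])

  res_iva <- iva_gl(mats, I1 = n_components, seed = seed + 1L)
  res_gig <- gigica(mats, n_components = n_components, seed = seed + 2L)
  mt <- cross_method_match(res_iva, res_gig, threshold = threshold)
  if (max(keep_list) > nrow(mt$pairs)) {
    stop("keep_list refers to more networks than were matched (",
         nrow(mt$pairs), ")")
  }
  pairs <- mt$pairs[keep_list, , drop = FALSE]
  n_net <- nrow(pairs)
  n_data <- length(mats)
  methods <- list(iva = list(res = res_iva, idx = pairs$est),
                  gigica = list(res = res_gig, idx = pairs$template))

  # per-network maps stack (datasets x voxels) and per-dataset TCs
  net_maps <- lapply(methods, function(mm) {
    lapply(seq_len(n_net), function(j) {
      do.call(rbind, lapply(mm$res$subject_maps, function(sm) {
        sm[mm$idx[j], ]
      }))
    })
  })
  net_tcs <- lapply(methods, function(mm) {
    lapply(seq_len(n_data), function(d) {
      mm$res$subject_tcs[[d]][, mm$idx, drop = FALSE]
    })
  })

  by_scan <- function(stack) lapply(1:3, function(s) {
    rows <- which(scan == s)
    rows <- rows[order(subject[rows])]
    stack[rows, , drop = FALSE]
  })

  reliability <- NULL
  for (method in names(methods)) {
    for (j in seq_len(n_net)) {
      masks <- lapply(names(methods), function(mn) {
        one_sample_t_fdr(net_maps[[mn]][[j]], q = q)$mask
      })
      joint <- Reduce(`&`, masks)
      if (!any(joint)) joint <- rep(TRUE, ncol(net_maps[[method]][[j]]))
      stacks <- by_scan(net_maps[[method]][[j]])
      reliability <- rbind(reliability, data.frame(
        method = method, network = j,
        short = network_reliability(stacks, joint, "short"),
        long = network_reliability(stacks, joint, "long")
      ))
    }
  }

  modularity <- NULL; conn_icc <- NULL; gmetrics <- NULL
  for (method in names(methods)) {
    fncs <- lapply(net_tcs[[method]], fnc)
    mean_fnc <- Reduce(`+`, fncs) / n_data
    mp_mean <- modularity_partition(mean_fnc)
    indiv <- lapply(fncs, modularity_partition)
    qs <- vapply(indiv, `[[`, numeric(1), "Q")
    parts <- lapply(indiv, `[[`, "partition")
    ami_pairs <- function(s1, s2) {
      i1 <- which(scan == s1); i2 <- which(scan %in% s2)
      vals <- NULL
      for (x in i1) for (y in i2) {
        if (ami_pairing == "matched" && subject[x] != subject[y]) next
        vals <- c(vals, ami(parts[[x]], parts[[y]]))
      }
      mean(vals)
    }
    up <- upper.tri(mean_fnc)
    fnc_rows <- do.call(rbind, lapply(fncs, function(f) f[up]))
    fnc_by_scan <- by_scan(fnc_rows)
    modularity <- rbind(modularity, data.frame(
      method = method, q_mean_fnc = mp_mean$Q, q_individual_mean = mean(qs),
      ami_short = ami_pairs(2, 3), ami_long = ami_pairs(1, c(2, 3))
    ))
    conn_icc <- rbind(conn_icc, data.frame(
      method = method, edge = seq_len(sum(up)),
      short = connectivity_icc(fnc_by_scan, "short"),
      long = connectivity_icc(fnc_by_scan, "long")
    ))
    gm <- lapply(fncs, function(f) {
      graph_metrics(threshold_sparsity(f, sparsity))
    })
    gmetrics <- rbind(gmetrics, data.frame(
      method = method, dataset = seq_len(n_data),
      node_strength = vapply(gm, `[[`, numeric(1), "node_strength"),
      clustering = vapply(gm, `[[`, numeric(1), "clustering"),
      global_eff = vapply(gm, `[[`, numeric(1), "global_eff"),
      local_eff = vapply(gm, `[[`, numeric(1), "local_eff")
    ))
  }
  out <- list(reliability = reliability, modularity = modularity,
              connectivity_icc = conn_icc, graph_metrics = gmetrics,
              match = mt)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("reliability", "modularity", "connectivity_icc",
                 "graph_metrics")) {
      write.csv(out[[nm]], file.path(outdir, paste0(nm, ".csv")),
                row.names = FALSE)
    }
  }
  out
}
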