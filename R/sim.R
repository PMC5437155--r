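#' Simulation of multi-subject fMRI-like data
#'
#' The simulator emulates the design used in simulation studies of
#' multi-subject decomposition methods: spatially compact Gaussian-blob
#' sources on a 148 x 148 pixel grid, shared across subjects up to random
#' translation / rotation / spread perturbations, mixed linearly with
#' haemodynamically smoothed random time courses, and corrupted with Rician
#' noise at a specified contrast-to-noise ratio (CNR).
#'
#' @name sim
NULL

# row-major flattening: voxel v = (row - 1) * width + col
flatten_map <- function(m) as.vector(t(m))

unflatten_map <- function(v, grid) {
  matrix(v, nrow = grid[1], ncol = grid[2], byrow = TRUE)
}

#' Simulation configuration
#'
#' Collects the parameters of a multi-subject simulation. Defaults follow the
#' reference design: 10 subjects, 8 sources on a 148 x 148 grid, 150 time
#' points at TR = 2 s, CNR = 2, translation SD 5 px, rotation SD 3 degrees,
#' spread (magnification) mean 3 and SD 0.03.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_sources integer vector, sources per subject (recycled to
#'   `n_subjects`); each >= 2.
#' @param grid integer pair, image height and width in pixels.
#' @param n_timepoints time points per subject (>= 2).
#' @param TR repetition time in seconds.
#' @param cnr contrast-to-noise ratio (> 0); ratio of in-source temporal
#'   signal SD to Gaussian noise SD.
#' @param translation_sd per-axis SD of the per-subject source translation, px.
#' @param rotation_sd SD of the per-subject source rotation, degrees.
#' @param spread_mean,spread_sd mean and SD of the per-subject magnification
#'   applied about the source centroid.
#' @param unique_source_flags logical per subject: does the subject carry a
#'   subject-unique source in addition to the common ones?
#' @param baseline positive offset added before Rician corruption (keeps the
#'   magnitude operation from rectifying signal).
#' @param seed integer seed controlling all randomness.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10, n_sources = 8, grid = c(148, 148),
                       n_timepoints = 150, TR = 2, cnr = 2,
                       translation_sd = 5, rotation_sd = 3,
                       spread_mean = 3, spread_sd = 0.03,
                       unique_source_flags = rep(FALSE, n_subjects),
                       baseline = 800, seed = 1L) {
  stopifnot(n_subjects >= 2, n_timepoints >= 2, cnr > 0,
            length(grid) == 2, all(grid >= 8))
  n_sources <- rep_len(as.integer(n_sources), n_subjects)
  stopifnot(all(n_sources >= 2))
  structure(list(
    n_subjects = as.integer(n_subjects), n_sources = n_sources,
    grid = as.integer(grid), n_timepoints = as.integer(n_timepoints),
    TR = TR, cnr = cnr, translation_sd = translation_sd,
    rotation_sd = rotation_sd, spread_mean = spread_mean,
    spread_sd = spread_sd,
    unique_source_flags = rep_len(unique_source_flags, n_subjects),
    baseline = baseline, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate common Gaussian-blob source maps
#'
#' Places `C` isotropic 2-D Gaussian blobs on a jittered lattice over the
#' grid, peak value 1, background 0. Blobs are spaced so that pairwise
#' spatial correlation stays below `overlap_cap`; exceeding the cap (too many
#' sources for the grid) is an error.
#'
#' @param C number of sources (>= 1).
#' @param grid integer pair (height, width).
#' @param seed integer seed.
#' @param sigma blob SD in pixels before any magnification. The default, 5 px,
#'   yields an effective SD of ~15 px after the standard x3 spread.
#' @param overlap_cap maximum allowed pairwise spatial correlation.
#' @return matrix (C x V) of flattened maps (row-major over row, column).
#' @export
make_base_maps <- function(C, grid = c(148, 148), seed = 1L, sigma = 5,
                           overlap_cap = 0.3) {
  stopifnot(C >= 1)
  with_seed(seed, {
    L <- ceiling(sqrt(C))
    # keep room for magnified blobs, but never more than a third of the grid
    margin <- min(max(4 * sigma, max(grid) / 6), 0.35 * min(grid))
    cy <- if (L > 1) seq(margin, grid[1] - margin, length.out = L) else
      (1 + grid[1]) / 2
    cx <- if (L > 1) seq(margin, grid[2] - margin, length.out = L) else
      (1 + grid[2]) / 2
    cells <- expand.grid(row = cy, col = cx)
    if (nrow(cells) < C) {
      stop("cannot place ", C, " sources under overlap cap ", overlap_cap)
    }
    idx <- sample.int(nrow(cells), C)
    jit <- if (L > 1) min(diff(cy)[1], diff(cx)[1]) / 8 else sigma
    centers <- cells[idx, , drop = FALSE] +
      matrix(runif(2 * C, -jit, jit), ncol = 2)
    rr <- matrix(seq_len(grid[1]), grid[1], grid[2])
    cc <- matrix(seq_len(grid[2]), grid[1], grid[2], byrow = TRUE)
    maps <- matrix(0, C, prod(grid))
    for (i in seq_len(C)) {
      d2 <- (rr - centers$row[i])^2 + (cc - centers$col[i])^2
      blob <- exp(-d2 / (2 * sigma^2))
      blob <- blob / max(blob)
      maps[i, ] <- flatten_map(blob)
    }
    if (C > 1) {
      pc <- abs_cor_rows(maps, maps)
      diag(pc) <- 0
      if (max(pc) > overlap_cap) {
        stop("source placement exceeds pairwise-overlap cap ", overlap_cap)
      }
    }
    maps
  })
}

#' Perturb a source map by translation, rotation, and spread
#'
#' Applies an affine transform about the map's intensity centroid: spatial
#' magnification by `spread`, rotation by `rotation` degrees, then translation
#' by `translation = c(dx, dy)` pixels (dx along columns, dy along rows).
#' Resampling is bilinear; content mapped from outside the grid is zero.
#'
#' @param base_map flattened map (length V) or height x width matrix.
#' @param translation numeric pair (dx, dy) in pixels.
#' @param rotation rotation angle in degrees (counter-clockwise).
#' @param spread magnification factor about the centroid (1 = identity).
#' @param grid integer pair (height, width); required when `base_map` is a
#'   vector.
#' @return perturbed map in the same form as the input.
#' @export
perturb_map <- function(base_map, translation = c(0, 0), rotation = 0,
                        spread = 1, grid = NULL) {
  vec_in <- !is.matrix(base_map)
  if (vec_in) {
    stopifnot(!is.null(grid))
    m <- unflatten_map(base_map, grid)
  } else {
    m <- base_map
    grid <- dim(m)
  }
  H <- grid[1]; W <- grid[2]
  tot <- sum(m)
  if (tot <= 0) stop("base_map must have positive mass")
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  c_r <- sum(rows * m) / tot
  c_c <- sum(cols * m) / tot
  th <- rotation * pi / 180
  # inverse mapping: output pixel -> source location in the input image
  dy <- rows - c_r - translation[2]
  dx <- cols - c_c - translation[1]
  src_c <- c_c + (cos(th) * dx + sin(th) * dy) / spread
  src_r <- c_r + (-sin(th) * dx + cos(th) * dy) / spread
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  samp <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- numeric(length(ri))
    out[ok] <- m[cbind(ri[ok], ci[ok])]
    out
  }
  v <- (1 - fr) * (1 - fc) * samp(r0, c0) +
       (1 - fr) * fc       * samp(r0, c0 + 1) +
       fr       * (1 - fc) * samp(r0 + 1, c0) +
       fr       * fc       * samp(r0 + 1, c0 + 1)
  out <- matrix(v, H, W)
  if (vec_in) flatten_map(out) else out
}

# canonical double-gamma haemodynamic response sampled at TR seconds
hrf_kernel <- function(TR, duration = 32) {
  t <- seq(0, duration, by = TR)
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / sum(abs(h))
}

#' Generate component time courses
#'
#' Each column is an independent white-noise process convolved with a
#' canonical haemodynamic-response kernel sampled at `TR`, then standardized
#' to zero mean and unit variance. The smoothing induces strong positive
#' lag-1 autocorrelation, as in resting-state fMRI component time courses.
#'
#' @param C number of time courses.
#' @param T_len number of time points (>= 8).
#' @param seed integer seed.
#' @param TR repetition time in seconds.
#' @return matrix (T_len x C), columns standardized.
#' @export
make_tcs <- function(C, T_len, seed = 1L, TR = 2) {
  stopifnot(T_len >= 8)
  with_seed(seed, {
    h <- hrf_kernel(TR)
    pad <- length(h)
    tcs <- matrix(0, T_len, C)
    for (j in seq_len(C)) {
      w <- rnorm(T_len + pad)
      s <- stats::convolve(w, rev(h), type = "open")[pad + seq_len(T_len)]
      tcs[, j] <- (s - mean(s)) / sd(s)
    }
    tcs
  })
}

#' Add Rician noise at a specified contrast-to-noise ratio
#'
#' The noisy signal is `sqrt((clean + baseline + n1)^2 + n2^2)` with `n1`,
#' `n2` independent zero-mean Gaussians of SD `sigma`, where `sigma` is set so
#' that the mean temporal SD of the noise-free signal over in-source voxels
#' (voxels whose temporal SD exceeds 10% of the maximum) divided by `sigma`
#' equals `cnr`. With a large `baseline` the magnitude operation never
#' rectifies the signal, so the effective noise is approximately Gaussian of
#' SD `sigma`.
#'
#' @param clean matrix (T x V) of noise-free signal.
#' @param cnr target contrast-to-noise ratio (> 0; `Inf` = no noise).
#' @param baseline positive offset added before corruption.
#' @param seed integer seed.
#' @return matrix (T x V), noisy non-negative data.
#' @export
add_rician_noise <- function(clean, cnr, baseline = 800, seed = 1L) {
  if (!is.finite(cnr)) {
    if (cnr <= 0) stop("cnr must be positive")
    return(clean + baseline)
  }
  if (cnr <= 0) stop("cnr must be positive")
  sds <- sqrt(colMeans(clean^2) - colMeans(clean)^2)
  in_src <- sds > 0.1 * max(sds)
  sigma <- mean(sds[in_src]) / cnr
  with_seed(seed, {
    n1 <- matrix(rnorm(length(clean), sd = sigma), nrow(clean))
    n2 <- matrix(rnorm(length(clean), sd = sigma), nrow(clean))
    sqrt((clean + baseline + n1)^2 + n2^2)
  })
}

# one subject's ground truth: perturbed maps + fresh TCs
simulate_subject_truth <- function(base_maps, cfg, subject, unique_src) {
  C_common <- nrow(base_maps)
  maps <- matrix(0, C_common + as.integer(unique_src), ncol(base_maps))
  labels <- rep("common", C_common)
  for (i in seq_len(C_common)) {
    maps[i, ] <- perturb_map(
      base_maps[i, ],
      translation = rnorm(2, 0, cfg$translation_sd),
      rotation = rnorm(1, 0, cfg$rotation_sd),
      spread = rnorm(1, cfg$spread_mean, cfg$spread_sd),
      grid = cfg$grid
    )
  }
  if (unique_src) {
    # subject-unique blob: fresh location uniform over the grid interior
    H <- cfg$grid[1]; W <- cfg$grid[2]
    sigma <- 5
    marg <- 3.5 * sigma * cfg$spread_mean / 2
    ctr <- c(runif(1, marg, H - marg), runif(1, marg, W - marg))
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    blob <- exp(-((rr - ctr[1])^2 + (cc - ctr[2])^2) / (2 * sigma^2))
    blob <- blob / max(blob)
    u <- perturb_map(flatten_map(blob), translation = c(0, 0), rotation = 0,
                     spread = rnorm(1, cfg$spread_mean, cfg$spread_sd),
                     grid = cfg$grid)
    maps[C_common + 1, ] <- u
    labels <- c(labels, "unique")
  }
  tcs <- make_tcs(nrow(maps), cfg$n_timepoints,
                  seed = sample.int(.Machine$integer.max, 1), TR = cfg$TR)
  structure(list(maps = maps, tcs = tcs, labels = labels),
            class = "ground_truth")
}

#' Generate a preset multi-subject simulation experiment
#'
#' Presets reproduce the standard study conditions (10 subjects, 148 x 148
#' grid, TR = 2 s):
#' \describe{
#'   \item{exp1_quality}{8 common sources, 150 time points, CNR set by `cnr`
#'     (the quality sweep covers 0.5 to 2 in steps of 0.1).}
#'   \item{exp1_quantity}{8 common sources, CNR = 2, time points set by
#'     `n_timepoints` (the quantity sweep covers 40 to 120 in steps of 20).}
#'   \item{exp2_varied_sources}{subjects 1-5 carry 8 sources, subjects 6-10
#'     only the first 7 (the 8th template is absent); CNR = 2, 150 points.}
#'   \item{exp2_model_order}{alias of exp1_quality at CNR = 2 (8-source data
#'     analysed at deliberately wrong model orders).}
#'   \item{exp3_unique}{7 common sources plus one subject-unique source per
#'     subject with large inter-subject spatial variability; CNR = 2.}
#' }
#'
#' @param preset preset name (see Details).
#' @param seed integer seed; generation is deterministic given
#'   `(preset, seed, cnr, n_timepoints)`.
#' @param cnr CNR used by exp1_quality (default 2).
#' @param n_timepoints time points used by exp1_quantity (default 150).
#' @return list with elements `datasets` (list of `subject_dataset`), `truth`
#'   (list of `ground_truth`), and `config` (`sim_config`).
#' @export
generate_experiment <- function(preset, seed = 1L, cnr = 2,
                                n_timepoints = 150) {
  presets <- c("exp1_quality", "exp1_quantity", "exp2_varied_sources",
               "exp2_model_order", "exp3_unique")
  if (!preset %in% presets) {
    stop("unknown preset '", preset, "'; available: ",
         paste(presets, collapse = ", "))
  }
  cfg <- switch(preset,
    exp1_quality = sim_config(cnr = cnr, seed = seed),
    exp1_quantity = sim_config(n_timepoints = n_timepoints, cnr = 2,
                               seed = seed),
    exp2_varied_sources = sim_config(n_sources = c(rep(8L, 5), rep(7L, 5)),
                                     cnr = 2, seed = seed),
    exp2_model_order = sim_config(cnr = 2, seed = seed),
    exp3_unique = sim_config(n_sources = 8L, cnr = 2, seed = seed,
                             unique_source_flags = rep(TRUE, 10))
  )
  with_seed(seed, {
    n_common <- if (preset == "exp3_unique") 7L else 8L
    base_maps <- make_base_maps(n_common, cfg$grid,
                                seed = sample.int(.Machine$integer.max, 1))
    datasets <- vector("list", cfg$n_subjects)
    truth <- vector("list", cfg$n_subjects)
    for (m in seq_len(cfg$n_subjects)) {
      n_keep_common <- min(cfg$n_sources[m] -
                             as.integer(cfg$unique_source_flags[m]), n_common)
      gt <- simulate_subject_truth(base_maps[seq_len(n_keep_common), ,
                                             drop = FALSE],
                                   cfg, m, cfg$unique_source_flags[m])
      clean <- gt$tcs %*% gt$maps
      data <- add_rician_noise(clean, cfg$cnr, cfg$baseline,
                               seed = sample.int(.Machine$integer.max, 1))
      datasets[[m]] <- structure(list(
        data = data, mask = rep(TRUE, ncol(data)),
        meta = list(subject = m, config = cfg, preset = preset)
      ), class = "subject_dataset")
      truth[[m]] <- gt
    }
    list(datasets = datasets, truth = truth, config = cfg)
  })
}
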