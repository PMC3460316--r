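#' Specify the synthetic scan generator
#'
#' Scans are generated as linear mixtures of spatial source maps: each source
#' has a smooth random low-frequency timecourse and a smooth spatial map; a
#' default-mode-like source carries an additive group difference in a stated
#' voxel block. Gaussian noise and a per-site multiplicative intensity gain
#' emulate acquisition heterogeneity. Scanner physics, motion and
#' physiological noise are not modelled.
#'
#' @param grid_dims three positive integers (nx, ny, nz).
#' @param voxel_mm voxel edge length in mm.
#' @param duration_s scan length in seconds.
#' @param tr_s repetition time in seconds; the scan has
#'   `round(duration_s / tr_s)` volumes.
#' @param n_sources number of spatial sources (>= 2).
#' @param dmn_effect additive group difference applied to the default-mode
#'   source map inside the effect block for ADHD participants.
#' @param noise_sd standard deviation of additive Gaussian noise (>= 0).
#' @param site_gain named numeric vector of per-site multiplicative gains.
#' @param baseline constant baseline intensity added to every voxel, as in
#'   real fMRI signal; percent-signal-change scaling divides by temporal
#'   means, so a nonzero baseline keeps those operations well defined. Set to
#'   0 for pure-mixture fixtures.
#' @return object of class `scan_gen_spec`.
#' @export
scan_gen_spec <- function(grid_dims = c(15L, 15L, 12L), voxel_mm = 3,
                          duration_s = 200, tr_s = 2, n_sources = 4L,
                          dmn_effect = 0, noise_sd = 0.5,
                          site_gain = c(siteA = 1), baseline = 100) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 1L))
    stop("`grid_dims` must be 3 positive integers")
  if (n_sources < 2L) stop("`n_sources` must be >= 2")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (duration_s <= 0 || tr_s <= 0) stop("durations must be positive")
  structure(list(grid_dims = grid_dims, voxel_mm = voxel_mm,
                 duration_s = duration_s, tr_s = tr_s,
                 n_sources = as.integer(n_sources), dmn_effect = dmn_effect,
                 noise_sd = noise_sd, site_gain = site_gain,
                 baseline = baseline),
            class = "scan_gen_spec")
}

# Smooth random 3D map: Gaussian blobs at seeded random centres.
random_source_map <- function(grid_dims, n_blobs = 3L, width_frac = 0.18) {
  nx <- grid_dims[1]; ny <- grid_dims[2]; nz <- grid_dims[3]
  co <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
  m <- numeric(nrow(co))
  w <- width_frac * mean(grid_dims)
  for (b in seq_len(n_blobs)) {
    cx <- stats::runif(1, 1, nx); cy <- stats::runif(1, 1, ny)
    cz <- stats::runif(1, 1, nz)
    amp <- stats::runif(1, 0.5, 1.5) * sample(c(-1, 1), 1)
    d2 <- (co$x - cx)^2 + (co$y - cy)^2 + (co$z - cz)^2
    m <- m + amp * exp(-d2 / (2 * w^2))
  }
  array(m, dim = grid_dims)
}

#' Ground truth for a synthetic cohort of scans
#'
#' Builds the spatial source maps (one flagged as the default-mode-like
#' network), the per-participant source weights, and the voxel block that
#' carries the injected group difference. This object is the recovery oracle
#' for the downstream decomposition and statistics modules.
#'
#' @param spec a [scan_gen_spec()].
#' @param n_participants number of participants.
#' @param seed integer seed.
#' @param weight_sd standard deviation of per-participant source weights
#'   around 1.
#' @param effect_block list with `corner` and `size` (3 integers each) giving
#'   the effect voxel block; default a block in the centre of the grid.
#' @return object of class `ground_truth` with fields `source_maps` (list of
#'   3D arrays), `subject_weights` (participants x sources),
#'   `dmn_index`, `effect_voxels` (logical 3D array) and `dmn_template`
#'   (the noiseless default-mode map, for component identification).
#' @export
make_ground_truth <- function(spec, n_participants, seed = 1L,
                              weight_sd = 0.15, effect_block = NULL) {
  stopifnot(inherits(spec, "scan_gen_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  g <- spec$grid_dims
  maps <- lapply(seq_len(spec$n_sources), function(k)
    random_source_map(g))
  dmn_index <- 1L
  if (is.null(effect_block)) {
    size <- pmax(1L, g %/% 5L)
    corner <- pmax(1L, g %/% 2L - size %/% 2L)
    effect_block <- list(corner = corner, size = size)
  }
  ev <- array(FALSE, dim = g)
  idx <- mapply(function(c0, s, d) seq.int(c0, min(c0 + s - 1L, d)),
                effect_block$corner, effect_block$size, g, SIMPLIFY = FALSE)
  ev[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  w <- matrix(stats::rnorm(n_participants * spec$n_sources, 1, weight_sd),
              n_participants, spec$n_sources)
  structure(list(source_maps = maps, subject_weights = w,
                 dmn_index = dmn_index, effect_voxels = ev,
                 dmn_template = maps[[dmn_index]], grid_dims = g),
            class = "ground_truth")
}

# Smooth band-limited timecourses, one column per source. Columns are
# orthogonalized (QR) so distinct networks have uncorrelated dynamics within
# a subject, as resting-state networks approximately do; without this a
# single subject's data cannot separate the sources.
random_timecourses <- function(n_t, n_sources, tr_s) {
  t_s <- (seq_len(n_t) - 1) * tr_s
  tc <- matrix(0, n_t, n_sources)
  for (k in seq_len(n_sources)) {
    freqs <- stats::runif(6L, 0.005, 0.08)
    phases <- stats::runif(6L, 0, 2 * pi)
    amps <- stats::runif(6L, 0.5, 1.5)
    for (j in seq_len(6L))
      tc[, k] <- tc[, k] + amps[j] * sin(2 * pi * freqs[j] * t_s + phases[j])
  }
  q <- qr.Q(qr(tc))
  # keep each source's original orientation and unit temporal sd
  for (k in seq_len(n_sources)) {
    if (sum(q[, k] * tc[, k]) < 0) q[, k] <- -q[, k]
    q[, k] <- q[, k] / stats::sd(q[, k])
  }
  q
}

#' Generate one synthetic 4D scan
#'
#' The scan is `gain * (baseline + sum_k tc_k (x) map_k,subject + noise)`
#' where
#' `map_k,subject` is `weights[k]` times the ground-truth source map, plus —
#' for the default-mode source only — the subject's additive effect
#' (`dmn_shift`) inside the effect block. The number of volumes is
#' `round(duration_s / tr_s)`.
#'
#' @param subject_weights numeric vector of length `n_sources`.
#' @param spec a [scan_gen_spec()].
#' @param truth a [make_ground_truth()] object on the same grid.
#' @param seed integer seed (drives timecourses and noise).
#' @param site name into `spec$site_gain` (default the first site).
#' @param dmn_shift additive default-mode effect for this subject (0 for
#'   controls; typically `spec$dmn_effect` for patients).
#' @return a [scan4d()].
#' @export
generate_scan <- function(subject_weights, spec, truth, seed,
                          site = names(spec$site_gain)[1], dmn_shift = 0) {
  stopifnot(inherits(spec, "scan_gen_spec"), inherits(truth, "ground_truth"))
  if (length(subject_weights) != spec$n_sources)
    stop("`subject_weights` must have one entry per source")
  if (!all(truth$grid_dims == spec$grid_dims))
    stop("ground truth grid does not match spec grid")
  if (!site %in% names(spec$site_gain)) stop("unknown site gain")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_t <- round(spec$duration_s / spec$tr_s)
  g <- spec$grid_dims
  n_vox <- prod(g)
  tc <- random_timecourses(n_t, spec$n_sources, spec$tr_s)
  maps <- matrix(0, n_vox, spec$n_sources)
  for (k in seq_len(spec$n_sources)) {
    m <- subject_weights[k] * truth$source_maps[[k]]
    if (k == truth$dmn_index && dmn_shift != 0)
      m <- m + dmn_shift * truth$effect_voxels
    maps[, k] <- as.vector(m)
  }
  sig <- maps %*% t(tc) + spec$baseline       # voxels x time
  if (spec$noise_sd > 0)
    sig <- sig + stats::rnorm(length(sig), 0, spec$noise_sd)
  gain <- spec$site_gain[[site]]
  scan4d(array(gain * sig, dim = c(g, n_t)), voxel_mm = spec$voxel_mm,
         tr_s = spec$tr_s)
}

#' Generate scans for a whole cohort
#'
#' Convenience wrapper drawing ground truth and one scan per participant.
#' ADHD participants (diagnosis other than `"control"`) receive the
#' `dmn_effect` shift of `spec` in the effect block; sites are recycled over
#' `names(spec$site_gain)` if the table's sites are not all present there.
#'
#' @param table participant data.frame (needs `diagnosis`, `site`).
#' @param spec a [scan_gen_spec()].
#' @param seed integer seed.
#' @return list with `scans` (list of [scan4d()]), `truth`
#'   (the [make_ground_truth()] object) and `is_patient` (logical vector).
#' @export
simulate_cohort_scans <- function(table, spec, seed = 1L) {
  n <- nrow(table)
  truth <- make_ground_truth(spec, n, seed = seed)
  known <- table$site %in% names(spec$site_gain)
  site_used <- ifelse(known, table$site, names(spec$site_gain)[1])
  is_patient <- table$diagnosis != "control"
  scans <- vector("list", n)
  for (i in seq_len(n)) {
    scans[[i]] <- generate_scan(
      truth$subject_weights[i, ], spec, truth, seed = seed + i,
      site = site_used[i],
      dmn_shift = if (is_patient[i]) spec$dmn_effect else 0)
  }
  list(scans = scans, truth = truth, is_patient = is_patient)
}

#' Two-group Gaussian simulation of group versus individual differences
#'
#' Draws `n_per_group` samples from N(0, 1) and N(delta, 1), computes the
#' pooled two-sample t statistic, and classifies every sample by the nearest
#' of the two empirical group means (equivalently, thresholding at their
#' midpoint). For large n the expected accuracy is `pnorm(delta / 2)`: a
#' mean separation chosen to give a huge t statistic in a large sample can
#' still classify individuals barely better than chance.
#'
#' @param n_per_group samples per group (>= 2).
#' @param delta standardized mean difference between the groups.
#' @param seed integer seed.
#' @return list with `samples` (data.frame `value`, `group`), `t` (two-sample
#'   t statistic), `df`, and `accuracy` (midpoint-classifier accuracy in %).
#' @export
simulate_two_gaussian_groups <- function(n_per_group, delta, seed = 1L) {
  if (n_per_group < 2) stop("`n_per_group` must be >= 2")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  x0 <- stats::rnorm(n_per_group, 0, 1)
  x1 <- stats::rnorm(n_per_group, delta, 1)
  n <- n_per_group
  sp2 <- ((n - 1) * stats::var(x0) + (n - 1) * stats::var(x1)) / (2 * n - 2)
  tval <- (mean(x1) - mean(x0)) / sqrt(sp2 * 2 / n)
  m0 <- mean(x0); m1 <- mean(x1)
  # nearest empirical group mean; orientation follows the sample means
  pred0 <- abs(x0 - m0) <= abs(x0 - m1)
  pred1 <- abs(x1 - m1) < abs(x1 - m0)
  acc <- 100 * (sum(pred0) + sum(pred1)) / (2 * n)
  list(samples = data.frame(value = c(x0, x1),
                            group = rep(c("A", "B"), each = n)),
       t = tval, df = 2L * n - 2L, accuracy = acc)
}
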