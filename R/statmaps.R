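#' Massively univariate two-sample t-map
#'
#' Pooled-variance two-sample t statistic at every in-mask voxel, comparing
#' the per-participant feature volumes of two groups (e.g. patients vs
#' controls on a component weighting map). `df = n_A + n_B - 2`. Voxels with
#' zero pooled variance get t = 0 with a warning.
#'
#' @param volumes_a,volumes_b lists of numeric 3D arrays on a common grid
#'   (>= 2 per group).
#' @param mask a [brain_mask()].
#' @param contrast tag recorded on the map.
#' @return a [stat_map()].
#' @export
two_sample_tmap <- function(volumes_a, volumes_b, mask,
                            contrast = "A-vs-B") {
  na <- length(volumes_a); nb <- length(volumes_b)
  if (na < 2L || nb < 2L) stop("need at least 2 volumes per group")
  keep <- as.vector(mask$data)
  xa <- matrix(vapply(volumes_a, function(v) as.vector(v)[keep],
                      numeric(sum(keep))), nrow = sum(keep))
  xb <- matrix(vapply(volumes_b, function(v) as.vector(v)[keep],
                      numeric(sum(keep))), nrow = sum(keep))
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tvals <- (ma - mb) / se
  if (any(se == 0)) {
    warning(sprintf("%d voxel(s) with zero pooled variance set to t = 0",
                    sum(se == 0)))
    tvals[se == 0] <- 0
  }
  vol <- array(0, dim = dim(mask$data))
  vol[mask$data] <- tvals
  stat_map(vol, df = na + nb - 2L, contrast = contrast, mask = mask)
}

#' One-sample (localizer) t-map
#'
#' Tests each voxel's values across participants against zero; `df = n - 1`.
#'
#' @param volumes list of numeric 3D arrays (>= 2).
#' @inheritParams two_sample_tmap
#' @return a [stat_map()].
#' @export
one_sample_tmap <- function(volumes, mask, contrast = "localizer") {
  n <- length(volumes)
  if (n < 2L) stop("need at least 2 volumes")
  keep <- as.vector(mask$data)
  x <- matrix(vapply(volumes, function(v) as.vector(v)[keep],
                     numeric(sum(keep))), nrow = sum(keep))
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (n - 1))
  tvals <- ifelse(s == 0, 0, m / (s / sqrt(n)))
  if (any(s == 0 & m != 0))
    warning("zero-variance voxels with nonzero mean set to t = 0")
  vol <- array(0, dim = dim(mask$data))
  vol[mask$data] <- tvals
  stat_map(vol, df = n - 1L, contrast = contrast, mask = mask)
}

#' Voxelwise |t| thresholding and cluster-size thresholding
#'
#' Zeroes voxels with `|t| <= theta_t`, then forms connected components
#' (26-neighbour connectivity by default) separately among the positive and
#' the negative suprathreshold voxels — contrasts are two-tailed, and mixing
#' signs within one cluster would corrupt cluster means — and zeroes every
#' component whose volume in mm^3 is below `theta_cs`.
#'
#' @param map a [stat_map()].
#' @param theta_t voxelwise |t| threshold (>= 0); 0 keeps all in-mask voxels.
#' @param theta_cs minimum cluster volume in mm^3; 0 disables size
#'   filtering.
#' @param connectivity 6, 18 or 26 (face / face+edge / face+edge+corner
#'   neighbours).
#' @return a [stat_map()] with sub-threshold voxels zeroed.
#' @export
threshold_and_size_filter <- function(map, theta_t, theta_cs,
                                      connectivity = 26L) {
  stopifnot(inherits(map, "stat_map"))
  x <- map$data
  x[abs(x) <= theta_t] <- 0   # strict |t| > theta_t survives; harmless at 0
  if (theta_cs > 0) {
    vox_vol <- map$voxel_mm^3
    min_vox <- ceiling(theta_cs / vox_vol)
    for (sgn in c(1, -1)) {
      lab <- label_components(x * sgn > 0, connectivity)
      if (lab$n_components > 0) {
        sizes <- tabulate(lab$labels[lab$labels > 0], lab$n_components)
        drop <- which(sizes < min_vox)
        if (length(drop)) x[lab$labels %in% drop & x * sgn > 0] <- 0
      }
    }
  }
  stat_map(x, df = map$df, contrast = map$contrast, mask = map$mask,
           voxel_mm = map$voxel_mm)
}

# Separable Gaussian smoothing of a 3D array; FWHM in mm. Kernel truncated at
# 3 sigma and renormalized at the edges.
gaussian_smooth3d <- function(vol, fwhm_mm, voxel_mm) {
  if (fwhm_mm <= 0) return(vol)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-half:half)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, dp[1])
    n <- dp[1]
    out <- matrix(0, n, ncol(m))
    wsum <- numeric(n)
    for (o in -half:half) {
      src <- pmin(pmax(seq_len(n) + o, 1L), n)
      valid <- (seq_len(n) + o) >= 1L & (seq_len(n) + o) <= n
      w <- kern[o + half + 1L]
      out[valid, ] <- out[valid, ] + w * m[src[valid], , drop = FALSE]
      wsum[valid] <- wsum[valid] + w
    }
    out <- out / wsum
    aperm(array(out, dp), order(perm))
  }
  for (ax in 1:3) vol <- smooth_axis(vol, ax)
  vol
}

#' Monte-Carlo calibration of the cluster-size threshold
#'
#' Estimates, by simulation under the null, the smallest cluster size s (in
#' voxels) such that the probability of observing any suprathreshold cluster
#' of at least s voxels is at most `alpha`. Each simulation draws two groups
#' of Gaussian white-noise volumes, smooths them to the stated FWHM,
#' variance-normalizes, computes the two-sample t-map, thresholds at
#' `|t| > theta_t` (sign-split components), and records the largest
#' component. With 3 mm voxels a threshold of 63 voxels corresponds to
#' 1,701 mm^3.
#'
#' @param mask a [brain_mask()].
#' @param smoothness_fwhm_mm spatial smoothness of the simulated null fields.
#' @param theta_t voxelwise |t| threshold.
#' @param alpha family-wise error target.
#' @param n_sim number of null simulations (>= 100).
#' @param seed integer seed.
#' @param group_sizes two group sizes for the simulated t-fields.
#' @param connectivity component connectivity.
#' @return minimum cluster size in voxels (integer >= 1).
#' @export
monte_carlo_cluster_threshold <- function(mask, smoothness_fwhm_mm, theta_t,
                                          alpha = 0.05, n_sim = 200L,
                                          seed = 1L,
                                          group_sizes = c(10L, 10L),
                                          connectivity = 26L) {
  if (n_sim < 100L) stop("`n_sim` must be >= 100")
  if (mask$n_voxels < 1L) stop("degenerate mask")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  g <- dim(mask$data)
  max_sizes <- integer(n_sim)
  for (s in seq_len(n_sim)) {
    draw_group <- function(n) lapply(seq_len(n), function(i) {
      v <- gaussian_smooth3d(array(stats::rnorm(prod(g)), dim = g),
                             smoothness_fwhm_mm, mask$voxel_mm)
      v / stats::sd(v)
    })
    tm <- suppressWarnings(
      two_sample_tmap(draw_group(group_sizes[1]), draw_group(group_sizes[2]),
                      mask, contrast = "null"))
    x <- tm$data
    x[abs(x) <= theta_t] <- 0
    biggest <- 0L
    for (sgn in c(1, -1)) {
      lab <- label_components(x * sgn > 0, connectivity)
      if (lab$n_components > 0)
        biggest <- max(biggest,
                       max(tabulate(lab$labels[lab$labels > 0],
                                    lab$n_components)))
    }
    max_sizes[s] <- biggest
  }
  # smallest s with P(max cluster >= s) <= alpha
  for (s_min in seq_len(max(max_sizes) + 1L)) {
    if (mean(max_sizes >= s_min) <= alpha) return(s_min)
  }
  max(max_sizes) + 1L
}
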