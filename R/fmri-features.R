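#' Temporal average (T Avg) feature extraction
#'
#' Replaces each voxel's timecourse by its temporal mean, reducing temporal
#' dimensionality from 370 to 1. Combined with window averaging and masking
#' this yields feature vectors of length 3,558 (r = 3) or 186 (r = 8).
#' Never combine with [pscs_tc()], which zeroes every temporal mean.
#'
#' @param scan a [scan4d()].
#' @param mask a [brain_mask()] on the scan grid (out-of-mask voxels are
#'   zero-filled in the output volume).
#' @return a [feature_volume_set()] with `eta = 1`.
#' @export
tavg <- function(scan, mask) {
  g <- grid_dims(scan)
  v <- array(rowMeans(matrix(scan$data, prod(g))), dim = g)
  v[!mask$data] <- 0
  feature_volume_set(list(v), mask, extractor = "tavg")
}

#' Fit a timecourse PCA basis
#'
#' Pools the timecourses of every in-mask voxel of every training scan as
#' observations (rows) and fits PCA on the resulting observations-by-time
#' matrix via the eigendecomposition of the time-by-time covariance of the
#' column-centred data. The sign of each component is fixed so its
#' largest-magnitude loading is positive. Fit this inside each
#' cross-validation training split when the projections feed a classifier.
#'
#' @param scans list of [scan4d()] (training participants), common temporal
#'   grid.
#' @param mask a [brain_mask()] on the scan grid.
#' @param n_components number of components to retain (default all).
#' @return object of class `timecourse_pca` with orthonormal `components`
#'   (time-by-k), per-timepoint `center`, `explained_variance` shares, and
#'   the number of observations used.
#' @export
fit_timecourse_pca <- function(scans, mask, n_components = NULL) {
  if (length(scans) < 1L) stop("need at least one scan")
  n_t <- n_timepoints(scans[[1]])
  keep <- as.vector(mask$data)
  obs <- do.call(rbind, lapply(scans, function(s) {
    if (n_timepoints(s) != n_t) stop("scans must share a temporal grid")
    matrix(s$data, prod(grid_dims(s)))[keep, , drop = FALSE]
  }))
  if (nrow(obs) < 2L) stop("need at least 2 observations to fit PCA")
  center <- colMeans(obs)
  xc <- sweep(obs, 2, center)
  cv <- crossprod(xc) / (nrow(xc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  k <- if (is.null(n_components)) n_t else min(n_components, n_t)
  comps <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                      # deterministic sign convention
    i <- which.max(abs(comps[, j]))
    if (comps[i, j] < 0) comps[, j] <- -comps[, j]
  }
  ev <- pmax(eg$values, 0)
  structure(list(components = comps, center = center,
                 explained_variance = (ev / sum(ev))[seq_len(k)],
                 n_obs = nrow(obs)),
            class = "timecourse_pca")
}

#' Project voxel timecourses onto a fitted PCA basis
#'
#' Per voxel, the centred timecourse is projected onto the first `k_keep`
#' components, giving `k_keep` coefficient volumes (370 -> 1 for PCA_1,
#' 370 -> 5 for PCA_1-5). With an r = 8 mask of 186 voxels the assembled
#' feature vectors have lengths 186 and 930.
#'
#' @param scan a [scan4d()].
#' @param basis a [fit_timecourse_pca()] object.
#' @param k_keep number of leading components (1 or 5 in the standard
#'   pipelines).
#' @param mask a [brain_mask()] on the scan grid.
#' @return a [feature_volume_set()] with `eta = k_keep`.
#' @export
project_pca <- function(scan, basis, k_keep, mask) {
  stopifnot(inherits(basis, "timecourse_pca"))
  if (k_keep < 1L || k_keep > ncol(basis$components))
    stop("`k_keep` must be between 1 and the number of fitted components")
  g <- grid_dims(scan)
  x <- matrix(scan$data, prod(g))
  co <- sweep(x, 2, basis$center) %*%
    basis$components[, seq_len(k_keep), drop = FALSE]
  vols <- lapply(seq_len(k_keep), function(k) {
    v <- array(co[, k], dim = g); v[!mask$data] <- 0; v
  })
  feature_volume_set(vols, mask, extractor = sprintf("pca1_%d", k_keep))
}

# DFT component indices (k = 1-based harmonic number) inside [f_lo, f_hi] Hz
# for an n_t-point series at sampling interval tr_s. Band ends inclusive.
band_components <- function(n_t, tr_s, f_lo = 0.001, f_hi = 0.1) {
  k <- seq_len(floor(n_t / 2))
  f <- k / (n_t * tr_s)
  k[f >= f_lo & f <= f_hi]
}

#' Band-limited FFT features
#'
#' Computes the unnormalized discrete Fourier transform of each voxel's
#' 370-point timecourse and keeps the modulus and phase angle of the 18
#' harmonics falling in the 0.001-0.1 Hz band (harmonics k = 1..18 at
#' frequencies k/185 Hz). Output order is the 18 moduli then the 18 phases
#' (radians in (-pi, pi\]), i.e. eta = 36; with an r = 8 mask of 186 voxels
#' the assembled feature vector has length 6,696.
#'
#' @param scan a [scan4d()] standardized to 370 points at 0.5 s.
#' @param mask a [brain_mask()] on the scan grid.
#' @return a [feature_volume_set()] with `eta = 36`.
#' @export
fft_band_features <- function(scan, mask) {
  check_temporal_grid(scan)
  g <- grid_dims(scan)
  ks <- band_components(n_timepoints(scan), scan$tr_s)
  x <- matrix(scan$data, prod(g))
  ft <- stats::mvfft(t(x))                 # time x voxels, DFT down columns
  sel <- t(ft[ks + 1L, , drop = FALSE])    # voxels x 18, harmonic k at row k+1
  vols <- vector("list", 2L * length(ks))
  for (j in seq_along(ks)) {
    vm <- array(Mod(sel[, j]), dim = g); vm[!mask$data] <- 0
    vp <- array(Arg(sel[, j]), dim = g); vp[!mask$data] <- 0
    vols[[j]] <- vm
    vols[[length(ks) + j]] <- vp
  }
  feature_volume_set(vols, mask, extractor = "fft")
}

#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' The per-voxel mean modulus over the 18 DFT harmonics in the 0.001-0.1 Hz
#' band; temporal dimensionality 370 -> 1. Feature vector lengths after
#' masking are 3,558 (r = 3) or 186 (r = 8).
#'
#' @inheritParams fft_band_features
#' @return a [feature_volume_set()] with `eta = 1`.
#' @export
alff <- function(scan, mask) {
  check_temporal_grid(scan)
  g <- grid_dims(scan)
  ks <- band_components(n_timepoints(scan), scan$tr_s)
  x <- matrix(scan$data, prod(g))
  ft <- stats::mvfft(t(x))
  m <- colMeans(Mod(ft[ks + 1L, , drop = FALSE]))
  v <- array(m, dim = g); v[!mask$data] <- 0
  feature_volume_set(list(v), mask, extractor = "alff")
}

check_temporal_grid <- function(scan, n_t = 370L, tr_s = 0.5) {
  if (n_timepoints(scan) != n_t || abs(scan$tr_s - tr_s) > 1e-9)
    stop(sprintf("expected %d time points at %.3g s; run standardize_time() first",
                 n_t, tr_s))
}

#' Assemble a participant feature vector from feature volumes
#'
#' Masks and flattens each of the `eta` feature volumes (x-fastest
#' lexicographic order) and concatenates them in k order. Names encode the
#' feature index and the in-mask voxel index as `k<k>_v<voxel>`. With
#' eta = 20 and a 186-voxel mask the vector has length 3,720.
#'
#' @param fvs a [feature_volume_set()].
#' @param mask optional [brain_mask()] overriding the set's mask (must share
#'   the grid).
#' @return named numeric vector of length `eta * mask$n_voxels`.
#' @export
assemble_feature_vector <- function(fvs, mask = fvs$mask) {
  stopifnot(inherits(fvs, "feature_volume_set"))
  if (!all(dim(mask$data) == dim(fvs$mask$data)))
    stop("mask grid does not match feature volumes")
  parts <- lapply(seq_len(fvs$eta), function(k) {
    v <- mask_and_flatten(fvs$volumes[[k]], mask)
    names(v) <- sprintf("k%d_v%d", k, seq_along(v))
    v
  })
  do.call(c, parts)
}

#' Participant-by-feature matrix for a whole cohort
#'
#' Applies [assemble_feature_vector()] to each participant's feature volume
#' set and stacks the rows.
#'
#' @param fvs_list list of [feature_volume_set()], one per participant.
#' @param mask optional common mask override.
#' @return numeric matrix, one row per participant.
#' @export
feature_matrix <- function(fvs_list, mask = NULL) {
  rows <- lapply(fvs_list, function(f)
    assemble_feature_vector(f, mask = if (is.null(mask)) f$mask else mask))
  do.call(rbind, rows)
}
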