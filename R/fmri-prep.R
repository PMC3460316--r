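#' Standardize a scan's temporal grid
#'
#' Truncates the scan to its first `target_duration_s` seconds and linearly
#' interpolates onto a uniform grid at `target_rate_hz`, anchored at the first
#' volume's acquisition time taken as 0. With the defaults every scan becomes
#' 370 volumes at a 0.5 s volume time. Scans shorter than the target duration
#' are refused rather than extrapolated.
#'
#' @param scan a [scan4d()].
#' @param target_duration_s target length in seconds.
#' @param target_rate_hz target sampling rate in Hz.
#' @return a [scan4d()] with `round(target_duration_s * target_rate_hz)`
#'   volumes and `tr_s = 1 / target_rate_hz`.
#' @export
standardize_time <- function(scan, target_duration_s = 185,
                             target_rate_hz = 2) {
  stopifnot(inherits(scan, "scan4d"))
  n_t <- n_timepoints(scan)
  if (n_t * scan$tr_s < target_duration_s)
    stop(sprintf("scan lasts %.1f s; refusing to extrapolate to %.1f s",
                 n_t * scan$tr_s, target_duration_s))
  new_tr <- 1 / target_rate_hz
  n_out <- round(target_duration_s * target_rate_hz)
  t_old <- (seq_len(n_t) - 1) * scan$tr_s
  t_new <- (seq_len(n_out) - 1) * new_tr
  # piecewise-linear weights onto the old grid, vectorized over voxels
  hi <- findInterval(t_new, t_old, all.inside = TRUE)
  lo <- hi
  up <- pmin(hi + 1L, n_t)
  w <- ifelse(up > lo, (t_new - t_old[lo]) / (t_old[up] - t_old[lo]), 0)
  g <- grid_dims(scan)
  x <- matrix(scan$data, nrow = prod(g), ncol = n_t)
  out <- x[, lo, drop = FALSE] * rep(1 - w, each = prod(g)) +
    x[, up, drop = FALSE] * rep(w, each = prod(g))
  scan4d(array(out, dim = c(g, n_out)), voxel_mm = scan$voxel_mm,
         tr_s = new_tr)
}

# Per-axis window bin index for SWA: floor(dim / r) windows of width r, the
# last window absorbing any remainder voxels.
swa_bins <- function(d, r) {
  n_out <- d %/% r
  b <- pmin((seq_len(d) - 1L) %/% r, n_out - 1L)
  list(bins = b + 1L, n_out = n_out)
}

#' Spatial window averaging (SWA)
#'
#' Block-mean spatial downsampling by an integer factor `r` along each axis.
#' The output grid is `floor(dim / r)` per axis; each output voxel is the
#' arithmetic mean of its window, with the remainder voxels on each axis
#' absorbed into the final (slightly larger) window. A 57 x 67 x 50 grid
#' becomes 19 x 22 x 16 (6,688 voxels) at `r = 3` and 7 x 8 x 6 (336 voxels)
#' at `r = 8`. For 4D input the averaging is applied independently at each
#' time point. The nominal voxel size scales by `r`.
#'
#' @param x [scan4d()], 3D array, or [brain_mask()] (masks are reduced by
#'   majority vote within each window).
#' @param r positive integer reduction factor, at most the smallest grid
#'   dimension. `r = 1` is the identity.
#' @return object of the same kind as `x` on the reduced grid.
#' @export
swa <- function(x, r) {
  r <- as.integer(r)
  if (inherits(x, "scan4d")) {
    g <- grid_dims(x)
    check_swa_r(r, g)
    red <- swa_array(x$data, r, g)
    return(scan4d(red, voxel_mm = x$voxel_mm * r, tr_s = x$tr_s))
  }
  if (inherits(x, "brain_mask")) {
    g <- dim(x$data)
    check_swa_r(r, g)
    frac <- swa_array(array(as.numeric(x$data), dim = g), r, g)
    prov <- c(x$provenance, list(swa_r = r, rule = "majority-vote"))
    return(brain_mask(frac >= 0.5, voxel_mm = x$voxel_mm * r,
                      provenance = prov))
  }
  if (is.array(x) && length(dim(x)) %in% c(3L, 4L)) {
    g <- dim(x)[1:3]
    check_swa_r(r, g)
    return(swa_array(x, r, g))
  }
  stop("`x` must be a scan4d, brain_mask, or 3D/4D array")
}

check_swa_r <- function(r, g) {
  if (length(r) != 1L || is.na(r) || r < 1L) stop("`r` must be a positive integer")
  if (r > min(g)) stop("`r` exceeds the smallest grid dimension")
}

swa_array <- function(a, r, g) {
  bx <- swa_bins(g[1], r); by <- swa_bins(g[2], r); bz <- swa_bins(g[3], r)
  out_g <- c(bx$n_out, by$n_out, bz$n_out)
  # linear output bin for every input voxel
  bin <- bx$bins +
    (rep(by$bins, each = g[1]) - 1L) * out_g[1] +
    (rep(bz$bins, each = g[1] * g[2]) - 1L) * out_g[1] * out_g[2]
  counts <- tabulate(bin, nbins = prod(out_g))
  is4d <- length(dim(a)) == 4L
  n_t <- if (is4d) dim(a)[4] else 1L
  m <- matrix(a, nrow = prod(g), ncol = n_t)
  sums <- rowsum(m, group = bin, reorder = TRUE)
  means <- sums / counts
  if (is4d) array(means, dim = c(out_g, n_t)) else array(means, dim = out_g)
}

#' Build a binary brain mask from mean intensity
#'
#' A voxel is in-brain iff its mean intensity — averaged across all supplied
#' scans and time points — is at least `threshold_frac` times the global mean
#' of the nonzero voxels of that average volume. Reduced-resolution masks for
#' SWA-processed data are obtained with `swa(mask, r)` (majority vote per
#' window).
#'
#' @param scans list of [scan4d()] on a common grid (at least one).
#' @param threshold_frac threshold as a fraction of the global nonzero mean.
#' @return a [brain_mask()] with the threshold recorded in its provenance.
#' @export
build_mask <- function(scans, threshold_frac = 0.5) {
  if (length(scans) < 1L) stop("need at least one scan")
  g <- grid_dims(scans[[1]])
  acc <- array(0, dim = g)
  for (s in scans) {
    if (!all(grid_dims(s) == g)) stop("scans must share a grid")
    acc <- acc + rowMeans(matrix(s$data, prod(g)))
  }
  mean_vol <- acc / length(scans)
  nz <- mean_vol[mean_vol != 0]
  if (length(nz) == 0) stop("all-zero scans: cannot build a mask")
  thr <- threshold_frac * mean(nz)
  brain_mask(array(mean_vol >= thr, dim = g),
             voxel_mm = scans[[1]]$voxel_mm,
             provenance = list(threshold_frac = threshold_frac,
                               threshold = thr))
}

#' Mask and flatten a 3D volume
#'
#' Extracts the in-mask voxels of a volume as a vector in fixed lexicographic
#' order — x fastest, then y, then z (R's native array order). The inverse
#' zero-fills voxels outside the mask.
#'
#' @param volume numeric 3D array.
#' @param mask a [brain_mask()] on the same grid.
#' @return `mask_and_flatten`: numeric vector of length `mask$n_voxels`.
#' @export
mask_and_flatten <- function(volume, mask) {
  if (!all(dim(volume) == dim(mask$data))) stop("volume/mask grid mismatch")
  as.vector(volume)[as.vector(mask$data)]
}

#' @rdname mask_and_flatten
#' @param values vector of length `mask$n_voxels`.
#' @return `unflatten`: 3D array with zeros outside the mask.
#' @export
unflatten <- function(values, mask) {
  if (length(values) != mask$n_voxels)
    stop("value vector does not match mask voxel count")
  out <- array(0, dim = dim(mask$data))
  out[mask$data] <- values
  out
}

#' Percent-signal-change scaling per voxel timecourse (PSCS-tc)
#'
#' Each voxel's timecourse x becomes `100 * (x - mu) / mu` with `mu` the
#' voxel's own temporal mean, so every output timecourse has mean zero. Only
#' in-mask voxels are checked and scaled; out-of-mask voxels are zeroed.
#' A zero temporal mean inside the mask is an error (the scaling is
#' undefined there).
#'
#' @param scan a [scan4d()].
#' @param mask optional [brain_mask()]; default is the full grid.
#' @return a [scan4d()] of percent-signal-change values.
#' @export
pscs_tc <- function(scan, mask = NULL) {
  g <- grid_dims(scan)
  keep <- if (is.null(mask)) rep(TRUE, prod(g)) else {
    if (!all(dim(mask$data) == g)) stop("scan/mask grid mismatch")
    as.vector(mask$data)
  }
  x <- matrix(scan$data, prod(g))
  mu <- rowMeans(x)
  bad <- keep & mu == 0
  if (any(bad))
    stop(sprintf("zero temporal mean inside mask at voxel %d",
                 which(bad)[1]))
  out <- matrix(0, nrow(x), ncol(x))
  out[keep, ] <- 100 * (x[keep, , drop = FALSE] - mu[keep]) / mu[keep]
  scan4d(array(out, dim = dim(scan$data)), voxel_mm = scan$voxel_mm,
         tr_s = scan$tr_s)
}

#' Percent-signal-change scaling per scan (PSCS-s)
#'
#' Every value becomes `100 * x / mu` with `mu` the mean over all in-mask
#' voxels and time points, so the scan-wide in-mask mean is 100 and a global
#' site gain cancels exactly. Between-voxel mean differences are preserved up
#' to the common scale. Out-of-mask voxels are zeroed.
#'
#' @param scan a [scan4d()].
#' @param mask a [brain_mask()] on the scan grid.
#' @return a [scan4d()].
#' @export
pscs_s <- function(scan, mask) {
  g <- grid_dims(scan)
  if (!all(dim(mask$data) == g)) stop("scan/mask grid mismatch")
  keep <- as.vector(mask$data)
  x <- matrix(scan$data, prod(g))
  mu <- mean(x[keep, , drop = FALSE])
  if (mu == 0) stop("zero scan-wide mean inside mask")
  out <- matrix(0, nrow(x), ncol(x))
  out[keep, ] <- 100 * x[keep, , drop = FALSE] / mu
  scan4d(array(out, dim = dim(scan$data)), voxel_mm = scan$voxel_mm,
         tr_s = scan$tr_s)
}
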