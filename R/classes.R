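#' Construct a 4D resting-state scan object
#'
#' A `scan4d` bundles a 4D intensity array (x, y, z, time) with the voxel edge
#' length in millimetres and the repetition time in seconds. All spatial
#' operations in the package assume an isotropic grid.
#'
#' @param data numeric 4D array with dimensions (nx, ny, nz, nt).
#' @param voxel_mm voxel edge length in mm (scalar, > 0).
#' @param tr_s repetition time (volume time) in seconds (scalar, > 0).
#' @return an object of class `scan4d`.
#' @export
scan4d <- function(data, voxel_mm = 3, tr_s = 0.5) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, time)")
  if (any(dim(data) < 1L)) stop("all scan dimensions must be >= 1")
  if (!is.numeric(voxel_mm) || length(voxel_mm) != 1L || voxel_mm <= 0)
    stop("`voxel_mm` must be a positive scalar")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0)
    stop("`tr_s` must be a positive scalar")
  structure(list(data = data, voxel_mm = voxel_mm, tr_s = tr_s),
            class = "scan4d")
}

#' @export
print.scan4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<scan4d> %d x %d x %d grid, %d time points, %.3g mm voxels, TR %.3g s\n",
              d[1], d[2], d[3], d[4], x$voxel_mm, x$tr_s))
  invisible(x)
}

#' @export
dim.scan4d <- function(x) dim(x$data)

n_timepoints <- function(scan) dim(scan$data)[4]
grid_dims <- function(x) {
  if (inherits(x, "scan4d")) dim(x$data)[1:3]
  else if (inherits(x, "brain_mask")) dim(x$data)
  else if (is.array(x)) dim(x)[1:3]
  else stop("cannot determine grid dimensions")
}

#' Construct a binary brain mask
#'
#' @param data logical 3D array; `TRUE` marks in-brain voxels.
#' @param voxel_mm voxel edge length in mm.
#' @param provenance free-form list describing how the mask was built
#'   (threshold fraction, reduction factor, ...). Recorded verbatim.
#' @return an object of class `brain_mask` with a `n_voxels` field.
#' @export
brain_mask <- function(data, voxel_mm = 3, provenance = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask `data` must be a logical 3D array")
  storage.mode(data) <- "logical"
  structure(list(data = data, voxel_mm = voxel_mm,
                 n_voxels = sum(data), provenance = provenance),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<brain_mask> %d x %d x %d grid, %d of %d voxels in brain\n",
              d[1], d[2], d[3], x$n_voxels, prod(d)))
  invisible(x)
}

#' Construct a per-participant feature volume set
#'
#' Holds the `eta` 3D feature volumes V_k for one participant produced by a
#' feature extractor (temporal average: eta = 1, five-component PCA: eta = 5,
#' band-limited FFT: eta = 36, ...). Voxels outside the mask are zero-filled.
#'
#' @param volumes list of `eta` numeric 3D arrays on a common grid.
#' @param mask `brain_mask` on the same grid.
#' @param extractor character tag naming the extractor.
#' @return object of class `feature_volume_set`.
#' @export
feature_volume_set <- function(volumes, mask, extractor = "unknown") {
  if (!is.list(volumes) || length(volumes) < 1L)
    stop("`volumes` must be a non-empty list of 3D arrays")
  g <- dim(mask$data)
  for (v in volumes) {
    if (!is.array(v) || length(dim(v)) != 3L || !all(dim(v) == g))
      stop("every feature volume must be a 3D array on the mask grid")
  }
  structure(list(volumes = volumes, mask = mask, eta = length(volumes),
                 extractor = extractor),
            class = "feature_volume_set")
}

#' Construct a voxelwise statistical map
#'
#' @param data numeric 3D array of t-values (zero outside the mask).
#' @param df degrees of freedom of the test.
#' @param contrast character tag, e.g. `"localizer"` or
#'   `"patients-vs-controls"`.
#' @param mask `brain_mask` on the same grid.
#' @param voxel_mm voxel edge length in mm.
#' @return object of class `stat_map`.
#' @export
stat_map <- function(data, df, contrast, mask, voxel_mm = mask$voxel_mm) {
  if (!all(dim(data) == dim(mask$data))) stop("map and mask grids differ")
  if (any(!is.finite(data[mask$data])))
    stop("t-values must be finite inside the mask")
  data[!mask$data] <- 0
  structure(list(data = data, df = df, contrast = contrast, mask = mask,
                 voxel_mm = voxel_mm),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> contrast '%s', df = %s, |t| range in mask [%.3g, %.3g]\n",
              x$contrast, format(x$df),
              min(abs(x$data[x$mask$data])), max(abs(x$data[x$mask$data]))))
  invisible(x)
}
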