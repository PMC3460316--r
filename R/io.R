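#' Read and write scans, masks and maps as NIfTI-1
#'
#' Scans are written as 4D volumes with the voxel size (mm) and repetition
#' time (s) recorded in the header pixdims; masks are written as uint8
#' volumes. A JSON sidecar can carry provenance (thresholds, reduction
#' factors) next to the image.
#'
#' @param scan a [scan4d()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_scan_nifti <- function(scan, path) {
  img <- RNifti::asNifti(scan$data)
  RNifti::pixdim(img) <- c(rep(scan$voxel_mm, 3), scan$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_scan_nifti
#' @export
read_scan_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  scan4d(array(as.numeric(img), dim = dim(img)), voxel_mm = pd[1],
         tr_s = if (length(pd) >= 4) pd[4] else 1)
}

#' @rdname write_scan_nifti
#' @param mask a [brain_mask()].
#' @export
write_mask_nifti <- function(mask, path) {
  arr <- array(as.integer(mask$data), dim = dim(mask$data))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(mask$voxel_mm, 3)
  RNifti::writeNifti(img, path, datatype = "uint8")
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(mask$provenance, sidecar, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_scan_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  sidecar <- paste0(path, ".json")
  prov <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  brain_mask(array(as.numeric(img) != 0, dim = dim(img)), voxel_mm = pd[1],
             provenance = prov)
}

#' Write a feature matrix with scaling metadata
#'
#' The matrix goes to CSV (header = feature names); the fitted encoding
#' (one-hot levels and min/max bounds), if attached, goes to a JSON sidecar.
#'
#' @param m numeric matrix from [encode_and_scale()] or [feature_matrix()].
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_feature_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  enc <- attr(m, "encoding")
  if (!is.null(enc))
    jsonlite::write_json(
      list(levels = enc$levels[!vapply(enc$levels, is.null, logical(1))],
           bounds = enc$bounds),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
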