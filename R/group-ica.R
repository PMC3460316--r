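#' Configuration for the group spatial ICA decomposition
#'
#' Defaults follow the standard two-stage formulation: 25 components kept in
#' each subject-level temporal PCA, 20 components kept in the group PCA, and
#' symmetric FastICA with the tanh nonlinearity, tolerance 1e-6 and at most
#' 1000 iterations from a seeded random start.
#'
#' @param n_subject_pcs components kept per subject.
#' @param n_group_pcs components kept at the group stage
#'   (<= `n_subject_pcs`).
#' @param nonlinearity currently `"tanh"`.
#' @param max_iter,tolerance FastICA iteration controls.
#' @param seed integer seed for the FastICA initialization.
#' @param on_nonconvergence `"warn"` (default) returns the final iterate with
#'   `converged = FALSE` and a warning; `"error"` aborts instead. When the
#'   model order exceeds the number of non-Gaussian signals in the data —
#'   routine when 20 components are extracted from data holding a handful of
#'   true networks — the Gaussian residual components have no stable fixed
#'   point and the symmetric iteration cannot meet the tolerance even though
#'   the structured components have long since locked in; failing hard by
#'   default would reject perfectly usable decompositions.
#' @return object of class `ica_config`.
#' @export
ica_config <- function(n_subject_pcs = 25L, n_group_pcs = 20L,
                       nonlinearity = "tanh", max_iter = 1000L,
                       tolerance = 1e-6, seed = 1L,
                       on_nonconvergence = c("warn", "error")) {
  if (n_group_pcs > n_subject_pcs)
    stop("`n_group_pcs` must not exceed `n_subject_pcs`")
  structure(list(n_subject_pcs = as.integer(n_subject_pcs),
                 n_group_pcs = as.integer(n_group_pcs),
                 nonlinearity = match.arg(nonlinearity, "tanh"),
                 max_iter = as.integer(max_iter), tolerance = tolerance,
                 seed = as.integer(seed),
                 on_nonconvergence = match.arg(on_nonconvergence)),
            class = "ica_config")
}

#' Subject-level temporal PCA reduction
#'
#' Reduces one participant's (timecourse-normalized, masked) scan from
#' `n_t` time points to `n` PCA components over the in-mask voxels. The scan
#' must be normalized with [pscs_tc()]; scan-level scaling does not remove
#' between-voxel mean differences and is unsuitable here. The reducing
#' transform is retained for back-reconstruction.
#'
#' @param scan a [scan4d()] after [pscs_tc()].
#' @param mask a [brain_mask()] on the scan grid.
#' @param n number of components (default 25; must not exceed the number of
#'   time points).
#' @return object of class `subject_reduction` with `Y` (n x voxels reduced
#'   data) and `F` (n_t x n reducing eigenvector matrix).
#' @export
subject_pca <- function(scan, mask, n = 25L) {
  x <- t(matrix(scan$data, prod(grid_dims(scan)))[as.vector(mask$data), ,
                                                  drop = FALSE])  # T x V
  n_t <- nrow(x)
  if (n_t < n) stop(sprintf("scan has %d time points; need >= %d", n_t, n))
  eg <- eigen(tcrossprod(x), symmetric = TRUE)        # T x T
  F_mat <- eg$vectors[, seq_len(n), drop = FALSE]
  structure(list(Y = crossprod(F_mat, x), F = F_mat,
                 eigenvalues = pmax(eg$values, 0)[seq_len(n)]),
            class = "subject_reduction")
}

# Symmetric FastICA with tanh nonlinearity on pre-whitened signals.
# zw: components x samples, rows white. Returns orthonormal unmixing W.
fastica_symm <- function(zw, max_iter, tol, seed, on_fail = "warn") {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(zw); p <- ncol(zw)
  sym_decorrelate <- function(w) {
    sw <- tcrossprod(w)
    eg <- eigen(sw, symmetric = TRUE)
    eg$vectors %*% diag(1 / sqrt(pmax(eg$values, .Machine$double.eps)),
                        n) %*% t(eg$vectors) %*% w
  }
  w <- sym_decorrelate(matrix(stats::rnorm(n * n), n, n))
  for (it in seq_len(max_iter)) {
    u <- w %*% zw
    gu <- tanh(u)
    w_new <- gu %*% t(zw) / p - diag(rowMeans(1 - gu^2), n) %*% w
    w_new <- sym_decorrelate(w_new)
    delta <- max(abs(abs(diag(w_new %*% t(w))) - 1))
    w <- w_new
    if (delta < tol) return(list(W = w, iterations = it, converged = TRUE))
  }
  msg <- sprintf(paste0("FastICA did not converge in %d iterations ",
                        "(last delta %.3g, tolerance %.3g)"),
                 max_iter, delta, tol)
  if (identical(on_fail, "error")) stop(msg)
  warning(msg)
  list(W = w, iterations = max_iter, converged = FALSE)
}

#' Group PCA + FastICA decomposition of subject reductions
#'
#' Temporally concatenates the subject reductions, retains `n_group_pcs`
#' components in a second PCA, and unmixes them into independent spatial
#' components with symmetric FastICA. Component signs are fixed so each group
#' map's largest-magnitude voxel is positive. The group reducing blocks are
#' retained per subject for GICA3 back-reconstruction.
#'
#' @param reductions list of [subject_pca()] objects (>= 2 subjects... a
#'   single subject is allowed and degenerates to its own decomposition).
#' @param config an [ica_config()].
#' @param mask the [brain_mask()] shared by the reductions.
#' @return object of class `group_ica` with `group_maps`
#'   (components x voxels), `unmixing` and `offset` (the affine map from
#'   concatenated reduced data to component maps), per-subject `G_blocks`,
#'   `n_subjects`, convergence info and the mask.
#' @export
group_ica_decompose <- function(reductions, config = ica_config(), mask) {
  m <- length(reductions)
  if (m < 1L) stop("need at least one subject reduction")
  n_s <- nrow(reductions[[1]]$Y)
  y <- do.call(rbind, lapply(reductions, `[[`, "Y"))   # (n_s * m) x V
  n_g <- config$n_group_pcs
  if (n_g > nrow(y))
    stop("`n_group_pcs` exceeds the stacked subject components")
  eg <- eigen(tcrossprod(y), symmetric = TRUE)
  G <- eg$vectors[, seq_len(n_g), drop = FALSE]        # (n_s*m) x n_g
  z <- crossprod(G, y)                                 # n_g x V
  # whiten the component-by-voxel signals (voxels are the samples)
  mu <- rowMeans(z)
  zc <- z - mu
  cz <- tcrossprod(zc) / ncol(zc)
  egz <- eigen(cz, symmetric = TRUE)
  K <- diag(1 / sqrt(pmax(egz$values, .Machine$double.eps)), n_g) %*%
    t(egz$vectors)
  fi <- fastica_symm(K %*% zc, config$max_iter, config$tolerance, config$seed,
                     on_fail = config$on_nonconvergence)
  unmix <- fi$W %*% K                                  # maps = unmix %*% (z - mu)
  offset <- as.vector(-unmix %*% mu)
  maps <- unmix %*% z + offset
  # deterministic sign: largest-|value| voxel of each group map positive
  for (k in seq_len(n_g)) {
    i <- which.max(abs(maps[k, ]))
    if (maps[k, i] < 0) {
      maps[k, ] <- -maps[k, ]
      unmix[k, ] <- -unmix[k, ]
      offset[k] <- -offset[k]
    }
  }
  g_blocks <- lapply(seq_len(m), function(i)
    G[(i - 1L) * n_s + seq_len(n_s), , drop = FALSE])
  structure(list(group_maps = maps, unmixing = unmix, offset = offset,
                 G_blocks = g_blocks, n_subjects = m, mask = mask,
                 iterations = fi$iterations, converged = fi$converged,
                 config = config),
            class = "group_ica")
}

#' GICA3 back-reconstruction of per-participant component maps
#'
#' Reconstructs subject-specific spatial maps from the group decomposition as
#' `S_i = M * unmix %*% (G_i' Y_i) + offset` (M subjects). By construction
#' the across-subject mean of the subject maps equals the group map exactly —
#' the defining property of this back-reconstruction scheme. Masked-out
#' voxels are zero-filled when maps are expanded to volumes.
#'
#' @param decomp a [group_ica_decompose()] result.
#' @param reductions the same list of [subject_pca()] objects used to fit it.
#' @return object of class `fc_map_set` with `subject_maps` (list of
#'   components-by-voxels matrices), `group_maps`, `mask`, and an
#'   as-yet-unset `dmn_index`.
#' @export
gica3_backreconstruct <- function(decomp, reductions) {
  stopifnot(inherits(decomp, "group_ica"))
  if (length(reductions) != decomp$n_subjects)
    stop("reductions do not match the fitted decomposition")
  m <- decomp$n_subjects
  subject_maps <- lapply(seq_len(m), function(i) {
    yi <- reductions[[i]]$Y
    if (is.null(yi)) stop("missing subject reduction")
    m * decomp$unmixing %*% crossprod(decomp$G_blocks[[i]], yi) +
      decomp$offset
  })
  structure(list(subject_maps = subject_maps,
                 group_maps = decomp$group_maps, mask = decomp$mask,
                 dmn_index = NA_integer_, dmn_correlation = NA_real_),
            class = "fc_map_set")
}

#' Identify the default-mode-like component by template correlation
#'
#' Automated surrogate for visual network identification: returns the
#' component whose group map has the largest absolute spatial correlation
#' with the template over in-mask voxels.
#'
#' @param maps an `fc_map_set` (or `group_ica`) object.
#' @param template 3D array on the mask grid (e.g. the generator's
#'   ground-truth default-mode map, or an atlas-derived template).
#' @param floor minimum acceptable |correlation|; below it an error is
#'   raised ("no DMN found").
#' @return the input `maps` with `dmn_index` and `dmn_correlation` set.
#' @export
identify_dmn <- function(maps, template, floor = 0.2) {
  mask <- maps$mask
  tv <- mask_and_flatten(template, mask)
  cors <- apply(maps$group_maps, 1, function(g) stats::cor(g, tv))
  best <- which.max(abs(cors))
  if (abs(cors[best]) < floor)
    stop(sprintf("no DMN found: best |correlation| %.3f below floor %.3f",
                 abs(cors[best]), floor))
  maps$dmn_index <- best
  maps$dmn_correlation <- cors[best]
  maps
}

#' Functional-connectivity feature vectors from component maps
#'
#' `FC_DMN` takes each participant's default-mode weighting map, applies
#' spatial window averaging at `r`, masks and flattens (lengths 3,558 at
#' r = 3 or 186 at r = 8 with the standard masks). `FC_1_20` does the same
#' for all components and concatenates them (length 3,720 for 20 components
#' on a 186-voxel mask).
#'
#' @param maps an `fc_map_set`; for `FC_DMN` the `dmn_index` must be set
#'   (see [identify_dmn()]).
#' @param mode `"FC_DMN"` or `"FC_1_20"`.
#' @param r spatial window averaging factor applied to the maps (1 = none).
#' @param reduced_mask [brain_mask()] on the reduced grid used for the final
#'   masking (e.g. `swa(mask, r)`).
#' @return numeric matrix, one row per participant.
#' @export
fc_features <- function(maps, mode = c("FC_DMN", "FC_1_20"), r = 1L,
                        reduced_mask = NULL) {
  mode <- match.arg(mode)
  mask <- maps$mask
  if (is.null(reduced_mask)) reduced_mask <- if (r == 1L) mask else swa(mask, r)
  comp_idx <- if (mode == "FC_DMN") {
    if (is.na(maps$dmn_index)) stop("identify the DMN component first")
    maps$dmn_index
  } else seq_len(nrow(maps$group_maps))
  rows <- lapply(maps$subject_maps, function(sm) {
    feats <- lapply(comp_idx, function(k) {
      vol <- unflatten(sm[k, ], mask)
      if (r > 1L) vol <- swa(vol, r)
      if (!all(dim(vol) == dim(reduced_mask$data)))
        stop("reduced mask grid does not match the averaged maps")
      mask_and_flatten(vol, reduced_mask)
    })
    do.call(c, feats)
  })
  do.call(rbind, rows)
}

#' Full functional-connectivity decomposition pipeline
#'
#' Masks and timecourse-normalizes each scan, runs the subject-level PCA, the
#' group PCA + FastICA decomposition, and GICA3 back-reconstruction.
#'
#' @param scans list of [scan4d()].
#' @param mask a [brain_mask()].
#' @param config an [ica_config()].
#' @return an `fc_map_set`.
#' @export
group_ica_pipeline <- function(scans, mask, config = ica_config()) {
  reductions <- lapply(scans, function(s)
    subject_pca(pscs_tc(s, mask), mask, n = config$n_subject_pcs))
  decomp <- group_ica_decompose(reductions, config, mask)
  gica3_backreconstruct(decomp, reductions)
}
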