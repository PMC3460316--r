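neighbor_offsets <- function(connectivity = 26L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

#' Label connected components of a 3D logical array
#'
#' Breadth-first labelling under 6-, 18- or 26-neighbour connectivity.
#'
#' @param x logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return list with `labels` (integer 3D array, 0 = background) and
#'   `n_components`.
#' @export
label_components <- function(x, connectivity = 26L) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  g <- dim(x)
  off <- neighbor_offsets(connectivity)
  labels <- array(0L, dim = g)
  fg <- which(x)
  if (length(fg) == 0) return(list(labels = labels, n_components = 0L))
  coords <- arrayInd(fg, g)
  coord_of <- matrix(0L, prod(g), 3L)
  coord_of[fg, ] <- coords
  lab <- 0L
  for (seed_vox in fg) {
    if (labels[seed_vox] != 0L) next
    lab <- lab + 1L
    labels[seed_vox] <- lab
    frontier <- seed_vox
    while (length(frontier)) {
      fc <- coord_of[frontier, , drop = FALSE]
      # all neighbours of the frontier, bounds-checked
      nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(j)
        sweep(fc, 2, off[j, ], `+`)))
      ok <- nb[, 1] >= 1L & nb[, 1] <= g[1] & nb[, 2] >= 1L &
        nb[, 2] <= g[2] & nb[, 3] >= 1L & nb[, 3] <= g[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique(nb[, 1] + (nb[, 2] - 1L) * g[1] +
                      (nb[, 3] - 1L) * g[1] * g[2])
      lin <- lin[x[lin] & labels[lin] == 0L]
      labels[lin] <- lab
      frontier <- lin
    }
  }
  list(labels = labels, n_components = lab)
}

#' Extract clusters from a thresholded statistical map
#'
#' Peak-based extraction: local maxima of |t| among the suprathreshold voxels
#' are found (a voxel is a peak if no suprathreshold neighbour has a strictly
#' larger |t|); peaks closer than `d_min` mm are merged, keeping the
#' higher-|t| peak (ties: lower linear index); every suprathreshold voxel is
#' assigned to its nearest surviving peak (Euclidean distance in mm, ties to
#' the lower-linear-index peak); clusters smaller than `v_min` mm^3 are
#' discarded; survivors are ordered by decreasing statistical mass (the sum
#' of |t| over member voxels) and the `n_clusters` most massive are kept.
#'
#' @param map a [stat_map()] that has already been |t|- and
#'   cluster-size-thresholded (see [threshold_and_size_filter()]).
#' @param d_min minimum inter-peak distance in mm.
#' @param v_min minimum extracted cluster volume in mm^3.
#' @param n_clusters how many clusters to keep (`Inf` for all).
#' @param connectivity neighbourhood used for peak detection.
#' @return object of class `cluster_set`: list of clusters, each with
#'   `voxels` (linear indices), `peak` (voxel coordinates), `volume_mm3` and
#'   `mass`; an empty suprathreshold set yields an empty cluster set.
#' @export
extract_clusters <- function(map, d_min = 0, v_min = 0, n_clusters = Inf,
                             connectivity = 26L) {
  stopifnot(inherits(map, "stat_map"))
  g <- dim(map$data)
  vox_vol <- map$voxel_mm^3
  at <- abs(map$data)
  supra <- which(at > 0)
  empty <- structure(list(clusters = list(), voxel_mm = map$voxel_mm,
                          grid = g), class = "cluster_set")
  if (length(supra) == 0) return(empty)
  co <- arrayInd(supra, g)
  off <- neighbor_offsets(connectivity)
  # peak = suprathreshold voxel with no strictly larger |t| neighbour
  is_peak <- vapply(seq_along(supra), function(i) {
    nb <- sweep(off, 2, co[i, ], `+`)
    ok <- nb[, 1] >= 1L & nb[, 1] <= g[1] & nb[, 2] >= 1L & nb[, 2] <= g[2] &
      nb[, 3] >= 1L & nb[, 3] <= g[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + (nb[, 2] - 1L) * g[1] + (nb[, 3] - 1L) * g[1] * g[2]
    all(at[lin] <= at[supra[i]])
  }, logical(1))
  peaks <- supra[is_peak]
  pco <- co[is_peak, , drop = FALSE]
  # merge peaks within d_min mm: keep higher |t|, tie -> lower linear index
  ord <- order(-at[peaks], peaks)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept)) {
      d_mm <- sqrt(colSums((t(pco[kept, , drop = FALSE]) - pco[i, ])^2)) *
        map$voxel_mm
      if (any(d_mm < d_min)) next
    }
    kept <- c(kept, i)
  }
  kp <- peaks[kept]
  kco <- pco[kept, , drop = FALSE]
  # order surviving peaks by linear index so distance ties resolve to the
  # lower-index peak deterministically
  pi_ord <- order(kp)
  kp <- kp[pi_ord]
  kco <- kco[pi_ord, , drop = FALSE]
  # assign every suprathreshold voxel to its nearest surviving peak
  d2 <- matrix(0, length(supra), length(kp))
  for (j in seq_along(kp))
    d2[, j] <- colSums((t(co) - kco[j, ])^2)
  nearest <- apply(d2, 1, function(r) which(r == min(r))[1])
  clusters <- lapply(seq_along(kp), function(j) {
    vox <- supra[nearest == j]
    list(voxels = vox, peak = kco[j, ], peak_index = kp[j],
         volume_mm3 = length(vox) * vox_vol, mass = sum(at[vox]))
  })
  clusters <- Filter(function(cl) cl$volume_mm3 >= v_min, clusters)
  if (length(clusters) == 0) return(empty)
  clusters <- clusters[order(-vapply(clusters, `[[`, numeric(1), "mass"))]
  if (is.finite(n_clusters) && length(clusters) > n_clusters)
    clusters <- clusters[seq_len(n_clusters)]
  structure(list(clusters = clusters, voxel_mm = map$voxel_mm, grid = g),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s)\n", length(x$clusters)))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  #%d: %d voxels (%.0f mm^3), mass %.2f, peak (%d, %d, %d)\n",
                i, length(cl$voxels), cl$volume_mm3, cl$mass,
                cl$peak[1], cl$peak[2], cl$peak[3]))
  }
  invisible(x)
}

#' Cluster summary table
#'
#' @param cs a `cluster_set`.
#' @return data.frame with peak coordinates in voxel and mm units, volume and
#'   statistical mass, in retained (mass) order.
#' @export
cluster_table <- function(cs) {
  if (length(cs$clusters) == 0)
    return(data.frame(cluster = integer(0), peak_x = integer(0),
                      peak_y = integer(0), peak_z = integer(0),
                      peak_x_mm = numeric(0), peak_y_mm = numeric(0),
                      peak_z_mm = numeric(0), n_voxels = integer(0),
                      volume_mm3 = numeric(0), mass = numeric(0)))
  do.call(rbind, lapply(seq_along(cs$clusters), function(i) {
    cl <- cs$clusters[[i]]
    data.frame(cluster = i, peak_x = cl$peak[1], peak_y = cl$peak[2],
               peak_z = cl$peak[3],
               peak_x_mm = cl$peak[1] * cs$voxel_mm,
               peak_y_mm = cl$peak[2] * cs$voxel_mm,
               peak_z_mm = cl$peak[3] * cs$voxel_mm,
               n_voxels = length(cl$voxels), volume_mm3 = cl$volume_mm3,
               mass = cl$mass)
  }))
}

#' Parse a cluster-feature parameter vector
#'
#' Accepts the bracketed syntax `"[2.582, 1701, inf, 30, 540]"` giving
#' `theta_t` (|t| threshold), `theta_cs` (minimum cluster volume, mm^3),
#' `n_clusters` (`inf` allowed), `d_min` (minimum inter-peak distance, mm)
#' and `v_min` (minimum extracted cluster volume, mm^3).
#'
#' @param x character scalar or numeric length-5 vector.
#' @param n_comparisons 1 (patients vs controls) or 2 (adds the
#'   subtype-vs-subtype contrast).
#' @return object of class `cluster_feature_spec`.
#' @export
cluster_feature_spec <- function(x, n_comparisons = 1L) {
  if (is.character(x)) {
    parts <- strsplit(gsub("\\[|\\]|\\s", "", x), ",")[[1]]
    x <- unname(vapply(parts, function(p)
      if (tolower(p) %in% c("inf", "∞")) Inf else as.numeric(p),
      numeric(1)))
  }
  if (length(x) != 5L || anyNA(x))
    stop("expected 5 values: [theta_t, theta_cs, n_clusters, d_min, v_min]")
  if (x[1] < 0 || x[2] < 0 || x[4] < 0 || x[5] < 0 || x[3] < 1)
    stop("invalid cluster feature parameters")
  if (!n_comparisons %in% 1:2) stop("`n_comparisons` must be 1 or 2")
  structure(list(theta_t = x[1], theta_cs = x[2], n_clusters = x[3],
                 d_min = x[4], v_min = x[5],
                 n_comparisons = as.integer(n_comparisons)),
            class = "cluster_feature_spec")
}

#' Cluster-mean feature vectors
#'
#' For each participant, for each statistical map's retained clusters, the
#' mean of the participant's corresponding feature volume over the cluster's
#' voxels; all means concatenated in (map, cluster) order. With 20 maps and
#' 10 clusters per map this yields 200 features per participant.
#'
#' @param volume_sets list over participants of lists of 3D feature volumes,
#'   one volume per statistical map (participant p's `V_k,p` for the map's
#'   k).
#' @param cluster_sets list of `cluster_set`s, one per statistical map, in
#'   the same map order.
#' @return numeric matrix, one row per participant, with `map<m>_cl<c>`
#'   column names.
#' @export
cluster_mean_features <- function(volume_sets, cluster_sets) {
  n_cl <- vapply(cluster_sets, function(cs) length(cs$clusters), integer(1))
  if (sum(n_cl) == 0) stop("no features selected: all cluster sets are empty")
  rows <- lapply(volume_sets, function(vols) {
    if (length(vols) != length(cluster_sets))
      stop("each participant needs one volume per statistical map")
    out <- numeric(0)
    nm <- character(0)
    for (m in seq_along(cluster_sets)) {
      cs <- cluster_sets[[m]]
      v <- vols[[m]]
      if (length(cs$clusters) && !all(dim(v) == cs$grid))
        stop("cluster grid does not match feature volume")
      for (ci in seq_along(cs$clusters)) {
        out <- c(out, mean(v[cs$clusters[[ci]]$voxels]))
        nm <- c(nm, sprintf("map%d_cl%d", m, ci))
      }
    }
    names(out) <- nm
    out
  })
  do.call(rbind, rows)
}

#' Robust voxel selection across leave-two-folds-out sub-iterations
#'
#' Given the thresholded map set `S_i` (computed without fold i) and the nine
#' thresholded sub-iteration sets `S_i,j` (computed without folds i and j),
#' retains in each `S_i` map only the voxels that are nonzero in the
#' corresponding map of all nine sub-iteration sets — a voxelwise logical AND
#' across the ten sets applied to the `S_i` values.
#'
#' @param s_i list of [stat_map()]s (already thresholded).
#' @param s_ij list of 9 lists of [stat_map()]s, each parallel to `s_i`.
#' @return list of [stat_map()]s, the filtered `S_i`.
#' @export
robust_voxel_selection <- function(s_i, s_ij) {
  if (length(s_ij) != 9L)
    stop("expected 9 sub-iteration map sets, got ", length(s_ij))
  for (sub in s_ij)
    if (length(sub) != length(s_i))
      stop("every sub-iteration set must contain one map per S_i map")
  lapply(seq_along(s_i), function(m) {
    keep <- s_i[[m]]$data != 0
    for (sub in s_ij) keep <- keep & (sub[[m]]$data != 0)
    x <- s_i[[m]]$data
    x[!keep] <- 0
    stat_map(x, df = s_i[[m]]$df, contrast = s_i[[m]]$contrast,
             mask = s_i[[m]]$mask, voxel_mm = s_i[[m]]$voxel_mm)
  })
}
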