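vol1 <- function(x) array(x, dim = c(1, 1, 1))

test_that("two-sample t-maps match the pooled closed form", {
  m <- full_mask(c(1, 1, 1))
  tm <- two_sample_tmap(lapply(c(1, 2, 3), vol1), lapply(c(4, 5, 6), vol1), m)
  # pooled sd = 1, se = sqrt(2/3), t = -3 / se
  expect_equal(tm$data[1, 1, 1], -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tm$df, 4L)
  # identical groups give t = 0
  same <- lapply(c(1, 2, 3), vol1)
  expect_equal(two_sample_tmap(same, same, m)$data[1, 1, 1], 0)
  # df = 666 for 239 patients vs 429 controls
  set.seed(1)
  tm2 <- two_sample_tmap(lapply(stats::rnorm(239), vol1),
                         lapply(stats::rnorm(429), vol1), m)
  expect_equal(tm2$df, 666L)
  # zero pooled variance warns and zeroes
  expect_warning(tz <- two_sample_tmap(lapply(c(1, 1), vol1),
                                       lapply(c(1, 1), vol1), m),
                 "zero pooled variance")
  expect_equal(tz$data[1, 1, 1], 0)
})

test_that("one-sample localizer t equals its closed form", {
  m <- full_mask(c(1, 1, 1))
  tm <- one_sample_tmap(lapply(c(1, 2, 3), vol1), m)
  expect_equal(tm$data[1, 1, 1], 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(tm$df, 2L)
  expect_equal(one_sample_tmap(lapply(c(0, 0), vol1), m)$data[1, 1, 1], 0)
  # shifting all volumes upward strictly increases t where sd > 0
  t_lo <- one_sample_tmap(lapply(c(1, 2, 3), vol1), m)$data[1, 1, 1]
  t_hi <- one_sample_tmap(lapply(c(2, 3, 4), vol1), m)$data[1, 1, 1]
  expect_gt(t_hi, t_lo)
})

test_that("t-map loop oracle on a random multi-voxel fixture", {
  g <- c(4, 3, 2)
  m <- full_mask(g)
  set.seed(2)
  va <- lapply(1:5, function(i) array(stats::rnorm(prod(g)), dim = g))
  vb <- lapply(1:7, function(i) array(stats::rnorm(prod(g)), dim = g))
  tm <- two_sample_tmap(va, vb, m)
  for (idx in c(1, 9, 24)) {
    a <- sapply(va, function(v) v[idx]); b <- sapply(vb, function(v) v[idx])
    oracle <- stats::t.test(a, b, var.equal = TRUE)$statistic
    expect_equal(tm$data[idx], unname(oracle), tolerance = 1e-10)
  }
})

test_that("cluster-size thresholding removes small components only", {
  g <- c(12, 12, 6)
  x <- array(0, dim = g)
  x[2:6, 2:6, 2:4] <- 3          # 75-voxel blob (> 63)
  x[9:12, 9:12, 5] <- 3          # 16-voxel blob
  x[1, 12, 6] <- 3               # isolated voxel
  m <- full_mask(g)
  tm <- stat_map(x, df = 10, contrast = "toy", mask = m)
  # 1701 mm^3 at 3 mm voxels is the 63-voxel rule
  out <- threshold_and_size_filter(tm, theta_t = 2, theta_cs = 1701)
  expect_true(all(out$data[2:6, 2:6, 2:4] == 3))
  expect_true(all(out$data[9:12, 9:12, 5] == 0))
  expect_equal(sum(out$data != 0), 75)
  # theta_t = 0, theta_cs = 0 is the identity
  id <- threshold_and_size_filter(tm, 0, 0)
  expect_equal(id$data, tm$data)
  # |t| threshold is strict
  thr <- threshold_and_size_filter(tm, 3, 0)
  expect_true(all(thr$data == 0))
})

test_that("positive and negative suprathreshold voxels cluster separately", {
  g <- c(8, 3, 3)
  x <- array(0, dim = g)
  x[1:4, 1, 1] <- 3
  x[5:8, 1, 1] <- -3             # adjacent but opposite sign
  tm <- stat_map(x, 10, "toy", full_mask(g))
  # each sign forms its own 4-voxel component; a 5-voxel minimum kills both
  out <- threshold_and_size_filter(tm, 2, theta_cs = 5 * 27)
  expect_true(all(out$data == 0))
  # a 4-voxel minimum keeps both
  out2 <- threshold_and_size_filter(tm, 2, theta_cs = 4 * 27)
  expect_equal(sum(out2$data != 0), 8)
})

test_that("connected-component labelling matches a brute-force oracle", {
  oracle_label <- function(x, connectivity) {
    g <- dim(x)
    lab <- array(0L, dim = g)
    nxt <- 0L
    off <- fcdiag:::neighbor_offsets(connectivity)
    for (v in which(x)) {
      if (lab[v] != 0L) next
      nxt <- nxt + 1L
      stack <- v
      while (length(stack)) {
        cur <- stack[1]; stack <- stack[-1]
        if (lab[cur] != 0L) next
        lab[cur] <- nxt
        cc <- arrayInd(cur, g)
        for (j in seq_len(nrow(off))) {
          nb <- cc + off[j, ]
          if (all(nb >= 1) && all(nb <= g)) {
            lv <- nb[1] + (nb[2] - 1) * g[1] + (nb[3] - 1) * g[1] * g[2]
            if (x[lv] && lab[lv] == 0L) stack <- c(stack, lv)
          }
        }
      }
    }
    lab
  }
  set.seed(3)
  for (conn in c(6L, 18L, 26L)) {
    x <- array(stats::runif(6 * 5 * 4) < 0.35, dim = c(6, 5, 4))
    got <- label_components(x, conn)
    want <- oracle_label(x, conn)
    expect_equal(got$n_components, max(want))
    # same partition up to label renumbering
    for (l in seq_len(got$n_components)) {
      members <- which(got$labels == l)
      expect_equal(length(unique(want[members])), 1L)
      expect_equal(sum(want == want[members[1]]), length(members))
    }
  }
})

test_that("cluster extraction orders by statistical mass with merging", {
  g <- c(20, 8, 6)
  co <- expand.grid(x = 1:g[1], y = 1:g[2], z = 1:g[3])
  bump <- function(cx, cy, cz, amp, w)
    amp * exp(-((co$x - cx)^2 + (co$y - cy)^2 + (co$z - cz)^2) / (2 * w^2))
  x <- array(bump(4, 4, 3, 6, 1.5) + bump(15, 4, 3, 4, 1.5), dim = g)
  x[x < 2] <- 0
  m <- full_mask(g)
  tm <- stat_map(x, 10, "toy", m)
  cs <- extract_clusters(tm, d_min = 9, v_min = 0, n_clusters = Inf)
  expect_length(cs$clusters, 2)
  # masses ordered by construction, verified by loop
  masses <- vapply(cs$clusters, `[[`, numeric(1), "mass")
  expect_true(masses[1] > masses[2])
  expect_equal(masses[1], sum(abs(x[cs$clusters[[1]]$voxels])))
  expect_equal(cs$clusters[[1]]$peak, c(4L, 4L, 3L))
  # volume bookkeeping
  expect_equal(cs$clusters[[1]]$volume_mm3,
               27 * length(cs$clusters[[1]]$voxels))
  # n_clusters = 1 keeps only the most massive
  cs1 <- extract_clusters(tm, d_min = 9, v_min = 0, n_clusters = 1)
  expect_length(cs1$clusters, 1)
  expect_equal(cs1$clusters[[1]]$peak, c(4L, 4L, 3L))
  # a d_min beyond the bump distance merges everything into one cluster
  cs_m <- extract_clusters(tm, d_min = 60, v_min = 0, n_clusters = Inf)
  expect_length(cs_m$clusters, 1)
  # empty map gives an empty set, not an error
  zm <- stat_map(array(0, dim = g), 10, "toy", m)
  expect_length(extract_clusters(zm)$clusters, 0)
})

test_that("single bump yields one cluster holding the global peak", {
  g <- c(9, 9, 5)
  co <- expand.grid(x = 1:9, y = 1:9, z = 1:5)
  x <- array(5 * exp(-((co$x - 5)^2 + (co$y - 5)^2 + (co$z - 3)^2) / 6),
             dim = g)
  x[x < 1] <- 0
  cs <- extract_clusters(stat_map(x, 10, "toy", full_mask(g)), d_min = 6)
  expect_length(cs$clusters, 1)
  expect_equal(cs$clusters[[1]]$peak, c(5L, 5L, 3L))
  expect_true(which.max(x) %in% cs$clusters[[1]]$voxels)
})

test_that("cluster parameter vectors parse from bracket syntax", {
  sp <- cluster_feature_spec("[2.582, 1701, inf, 30, 540]",
                             n_comparisons = 2)
  expect_equal(sp$theta_t, 2.582)
  expect_equal(sp$theta_cs, 1701)
  expect_true(is.infinite(sp$n_clusters))
  expect_equal(sp$d_min, 30)
  expect_equal(sp$v_min, 540)
  expect_equal(sp$n_comparisons, 2L)
  expect_error(cluster_feature_spec("[1, 2, 3]"), "5 values")
})

test_that("cluster-mean features concatenate per-map means", {
  g <- c(6, 6, 4)
  m <- full_mask(g)
  # 20 maps x 10 clusters each = 200 features per participant
  x <- array(0, dim = g)
  x[1:20 * 7] <- 5                              # 20 scattered voxels
  tm <- stat_map(x, 10, "toy", m)
  cs10 <- extract_clusters(tm, d_min = 0, v_min = 0, n_clusters = 10)
  cluster_sets <- rep(list(cs10), 20)
  vols <- lapply(1:3, function(p) lapply(1:20, function(k)
    array(p * k, dim = g)))
  feats <- cluster_mean_features(vols, cluster_sets)
  expect_equal(dim(feats), c(3L, 200L))
  expect_true(all(feats[2, 1:10] == 2))
  # single-voxel cluster returns that voxel's value; loop oracle
  set.seed(4)
  rv <- array(stats::rnorm(prod(g)), dim = g)
  feats2 <- cluster_mean_features(list(list(rv)), list(cs10))
  oracle <- sapply(cs10$clusters, function(cl) mean(rv[cl$voxels]))
  expect_equal(unname(feats2[1, ]), oracle, tolerance = 1e-12)
  # empty cluster sets across all maps error
  empty_cs <- extract_clusters(stat_map(array(0, dim = g), 10, "t", m))
  expect_error(cluster_mean_features(vols, rep(list(empty_cs), 20)),
               "no features")
})

test_that("robust selection is the voxelwise AND across the ten map sets", {
  g <- c(5, 5, 4)
  m <- full_mask(g)
  set.seed(5)
  mk_maps <- function() lapply(1:2, function(k) {
    x <- array(stats::rnorm(prod(g)), dim = g)
    x[abs(x) < 0.8] <- 0
    stat_map(x, 10, "toy", m)
  })
  s_i <- mk_maps()
  s_ij <- lapply(1:9, function(j) mk_maps())
  out <- robust_voxel_selection(s_i, s_ij)
  for (k in 1:2) {
    keep <- s_i[[k]]$data != 0
    for (j in 1:9) keep <- keep & (s_ij[[j]][[k]]$data != 0)
    oracle <- s_i[[k]]$data * keep
    expect_equal(out[[k]]$data, oracle)
    # retained voxels are a subset of the input voxels
    expect_true(all(which(out[[k]]$data != 0) %in% which(s_i[[k]]$data != 0)))
  }
  # idempotence: all sub-iterations equal to S_i leave it unchanged
  same <- robust_voxel_selection(s_i, rep(list(s_i), 9))
  expect_equal(same[[1]]$data, s_i[[1]]$data)
  # one empty sub-iteration empties the output
  empty <- lapply(1:2, function(k) stat_map(array(0, dim = g), 10, "e", m))
  gone <- robust_voxel_selection(s_i, c(rep(list(s_i), 8), list(empty)))
  expect_true(all(gone[[1]]$data == 0) && all(gone[[2]]$data == 0))
  expect_error(robust_voxel_selection(s_i, rep(list(s_i), 5)), "9 sub")
})

test_that("raising the |t| threshold shrinks the robust-selected set", {
  g <- c(5, 5, 4)
  m <- full_mask(g)
  set.seed(6)
  raw <- lapply(1:10, function(i)
    array(stats::rnorm(prod(g)), dim = g))
  sets <- function(theta) {
    maps <- lapply(raw, function(x) {
      y <- x; y[abs(y) <= theta] <- 0
      list(stat_map(y, 10, "toy", m))
    })
    robust_voxel_selection(maps[[1]], maps[2:10])
  }
  lo <- sets(0.5)[[1]]$data
  hi <- sets(1.0)[[1]]$data
  expect_true(all(which(hi != 0) %in% which(lo != 0)))
})

test_that("Monte-Carlo threshold behaves at its limits", {
  m <- full_mask(c(6, 6, 4))
  # alpha = 1 demands no filtering
  expect_equal(monte_carlo_cluster_threshold(m, 0, theta_t = 2, alpha = 1,
                                             n_sim = 100, seed = 1), 1)
  # unsmoothed noise at a high threshold leaves isolated voxels at most
  thr <- monte_carlo_cluster_threshold(m, 0, theta_t = 4.5, alpha = 0.05,
                                       n_sim = 100, seed = 2,
                                       group_sizes = c(8, 8))
  expect_lte(thr, 2)
  expect_error(monte_carlo_cluster_threshold(m, 0, 2, n_sim = 10), ">= 100")
})

test_that("smoothness never decreases the calibrated cluster threshold", {
  m <- full_mask(c(8, 8, 6))
  thr_sharp <- mean(sapply(1:3, function(s)
    monte_carlo_cluster_threshold(m, 3, theta_t = 2, alpha = 0.05,
                                  n_sim = 100, seed = s,
                                  group_sizes = c(8, 8))))
  thr_smooth <- mean(sapply(1:3, function(s)
    monte_carlo_cluster_threshold(m, 6, theta_t = 2, alpha = 0.05,
                                  n_sim = 100, seed = s,
                                  group_sizes = c(8, 8))))
  expect_gte(thr_smooth, thr_sharp)
})
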