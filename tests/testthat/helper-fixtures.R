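# Shared fixture builders. Everything is generated in code at test time.

full_mask <- function(g, voxel_mm = 3) {
  brain_mask(array(TRUE, dim = g), voxel_mm = voxel_mm)
}

# mask with exactly n in-brain voxels (first n in x-fastest order)
mask_with_n <- function(g, n, voxel_mm = 3) {
  m <- array(FALSE, dim = g)
  m[seq_len(n)] <- TRUE
  brain_mask(m, voxel_mm = voxel_mm)
}

random_scan <- function(g = c(6, 6, 5), n_t = 20, tr_s = 0.5, voxel_mm = 3,
                        seed = 1, offset = 100) {
  set.seed(seed)
  scan4d(array(stats::rnorm(prod(g) * n_t) + offset, dim = c(g, n_t)),
         voxel_mm = voxel_mm, tr_s = tr_s)
}

# standardized scan (370 points at 0.5 s) with optional deterministic content
standardized_scan <- function(g = c(4, 4, 3), seed = 1, offset = 100) {
  random_scan(g, n_t = 370, tr_s = 0.5, seed = seed, offset = offset)
}

# small cohort with an injected default-mode group effect
toy_effect_cohort <- function(n_per_group = 6, grid = c(10, 10, 8),
                              dmn_effect = 1.0, noise_sd = 0.3, seed = 7) {
  sg <- scan_gen_spec(grid_dims = grid, duration_s = 185, tr_s = 2,
                      n_sources = 4, noise_sd = noise_sd,
                      dmn_effect = dmn_effect)
  tab <- data.frame(diagnosis = rep(c("control", "ADHD-C"),
                                    each = n_per_group),
                    site = "siteA")
  sim <- simulate_cohort_scans(tab, sg, seed = seed)
  sim$mask <- full_mask(grid)
  sim
}

# brute-force window-mean oracle for SWA (remainder absorbed in last window)
swa_oracle <- function(a, r) {
  g <- dim(a)
  out_g <- g %/% r
  out <- array(0, dim = out_g)
  for (i in seq_len(out_g[1])) for (j in seq_len(out_g[2]))
    for (k in seq_len(out_g[3])) {
      xs <- ((i - 1) * r + 1):(if (i == out_g[1]) g[1] else i * r)
      ys <- ((j - 1) * r + 1):(if (j == out_g[2]) g[2] else j * r)
      zs <- ((k - 1) * r + 1):(if (k == out_g[3]) g[3] else k * r)
      out[i, j, k] <- mean(a[xs, ys, zs])
    }
  out
}
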