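test_that("generated participant tables reproduce the cohort composition", {
  spec <- training_cohort_spec(seed = 42)
  tab <- generate_participants(spec)
  expect_equal(nrow(tab), 668)
  expect_equal(sum(tab$diagnosis == "control"), 429)
  expect_equal(sum(tab$diagnosis == "ADHD-C"), 141)
  expect_equal(sum(tab$diagnosis == "ADHD-I"), 98)
  # majority-class fraction is 429/668
  expect_equal(chance_baseline(tab$diagnosis), 100 * 429 / 668)
  # fixed documented header
  expect_identical(names(tab),
                   c("participant_id", "diagnosis", "site", "age", "gender",
                     "handedness", "medication", "iq_measure", "verbal_iq",
                     "performance_iq", "full2_iq", "full4_iq"))
})

test_that("empty cohort gives an empty table with the full header", {
  spec <- training_cohort_spec(seed = 1)
  spec$n_per_group[] <- 0L
  tab <- generate_participants(spec)
  expect_equal(nrow(tab), 0)
  expect_equal(ncol(tab), 12)
})

test_that("the Edinburgh site emits continuous handedness and no IQ", {
  tab <- generate_participants(training_cohort_spec(seed = 7))
  ed <- tab$site == "NeuroIMAGE"
  expect_gt(sum(ed), 0)
  h <- tab$handedness[ed]
  h <- h[!is.na(h)]
  expect_true(all(h >= -100 & h <= 100))
  expect_true(any(h != round(h)))        # genuinely continuous scores
  expect_true(all(is.na(tab$verbal_iq[ed])))
  expect_true(all(is.na(tab$full4_iq[ed])))
  # other sites stay categorical
  other <- tab$handedness[!ed]
  expect_true(all(other[!is.na(other)] %in% c(0, 1, 2)))
})

test_that("configured missingness matches its binomial expectation", {
  spec <- training_cohort_spec(
    seed = 3, missingness = list(NYU = c(verbal_iq = 0.2)))
  spec$n_per_group <- c(control = 2000L, `ADHD-C` = 0L, `ADHD-I` = 0L)
  tab <- generate_participants(spec)
  nyu <- tab[tab$site == "NYU", ]
  n <- nrow(nyu)
  expect_gt(n, 100)
  p_hat <- mean(is.na(nyu$verbal_iq))
  tol <- 3 * sqrt(0.2 * 0.8 / n)
  expect_lt(abs(p_hat - 0.2), tol)
})

test_that("table marginals converge to spec parameters (3-sd checks)", {
  spec <- training_cohort_spec(seed = 11)
  spec$n_per_group <- c(control = 4000L, `ADHD-C` = 0L, `ADHD-I` = 0L)
  tab <- generate_participants(spec)
  n <- nrow(tab)
  p_f <- mean(tab$gender == "F")
  expect_lt(abs(p_f - 0.476), 3 * sqrt(0.476 * 0.524 / n))
  expect_lt(abs(mean(tab$age) - 12.4), 3 * 3.3 / sqrt(n))
  p_peking <- mean(tab$site == "PekingU")
  p0 <- spec$site_props["control", "PekingU"]
  expect_lt(abs(p_peking - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("invalid cohort specs are rejected", {
  spec <- training_cohort_spec(seed = 1)
  bad <- spec$site_props
  bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(cohort_spec(spec$n_per_group, spec$sites, bad,
                           spec$age_params, spec$gender_props,
                           spec$handedness_props, spec$edinburgh_site,
                           spec$iq_params, spec$iq_availability,
                           spec$iq_measure_by_site, spec$medication_props),
               "sum to 1")
  expect_error(cohort_spec(c(control = -1L, `ADHD-C` = 0L, `ADHD-I` = 0L),
                           spec$sites, spec$site_props, spec$age_params,
                           spec$gender_props, spec$handedness_props,
                           spec$edinburgh_site, spec$iq_params,
                           spec$iq_availability, spec$iq_measure_by_site,
                           spec$medication_props),
               "non-negative")
})

test_that("participant CSV round trip preserves data and missingness", {
  tab <- generate_participants(training_cohort_spec(seed = 5))
  path <- tempfile(fileext = ".csv")
  write_participants(tab, path)
  back <- read_participants(path)
  expect_equal(back$age, tab$age, tolerance = 1e-12)
  expect_identical(is.na(back$verbal_iq), is.na(tab$verbal_iq))
  expect_identical(attr(back, "edinburgh_site"), "NeuroIMAGE")
  unlink(path)
})

test_that("scan generation follows the linear mixing model", {
  g <- c(6, 6, 5)
  # noiseless single source: rank-1 space-time structure
  sg <- scan_gen_spec(grid_dims = g, duration_s = 40, tr_s = 2,
                      n_sources = 2, noise_sd = 0, baseline = 0)
  truth <- make_ground_truth(sg, 1, seed = 2)
  sc <- generate_scan(c(1, 0), sg, truth, seed = 9)
  expect_equal(dim(sc$data)[4], 20)
  m <- matrix(sc$data, prod(g))
  sv <- svd(m, nu = 0, nv = 0)$d
  expect_lt(sv[2] / sv[1], 1e-10)
  # every volume is a scalar multiple of the source map
  map1 <- as.vector(truth$source_maps[[1]])
  for (t in c(1, 10, 20))
    expect_equal(abs(cor(m[, t], map1)), 1, tolerance = 1e-10)
})

test_that("site gain is exactly multiplicative and seeds are reproducible", {
  g <- c(5, 5, 4)
  sg1 <- scan_gen_spec(grid_dims = g, duration_s = 40, tr_s = 2,
                       n_sources = 2, noise_sd = 0.3,
                       site_gain = c(a = 1, b = 2))
  truth <- make_ground_truth(sg1, 1, seed = 4)
  s_a <- generate_scan(c(1, 1), sg1, truth, seed = 3, site = "a")
  s_b <- generate_scan(c(1, 1), sg1, truth, seed = 3, site = "b")
  expect_equal(s_b$data, 2 * s_a$data, tolerance = 1e-12)
  s_a2 <- generate_scan(c(1, 1), sg1, truth, seed = 3, site = "a")
  expect_identical(s_a$data, s_a2$data)   # bit-identical under the same seed
})

test_that("least-squares regression recovers the generating weights", {
  g <- c(6, 6, 5)
  sg <- scan_gen_spec(grid_dims = g, duration_s = 100, tr_s = 2,
                      n_sources = 3, noise_sd = 0.05, baseline = 0)
  truth <- make_ground_truth(sg, 1, seed = 6)
  w_true <- c(1.3, 0.7, 1.0)
  sc <- generate_scan(w_true, sg, truth, seed = 12)
  # oracle: regress the scan onto the space-time regressors map_k (x) tc_k.
  # The generator's timecourses are recovered by projecting the data onto
  # each map and orthonormalizing is unnecessary at this noise level; we
  # instead estimate per-source scale by least squares on the outer-product
  # design evaluated per time point.
  m <- matrix(sc$data, prod(g))
  maps <- sapply(truth$source_maps, as.vector)
  co <- t(qr.solve(maps, m))              # time x sources: w_k * tc_k(t)
  w_hat <- apply(co, 2, stats::sd)        # tc_k has unit temporal sd
  expect_equal(w_hat, w_true, tolerance = 0.05)
})

test_that("dimension mismatches in scan generation error", {
  sg <- scan_gen_spec(grid_dims = c(5, 5, 4), n_sources = 2)
  truth <- make_ground_truth(sg, 1, seed = 1)
  expect_error(generate_scan(c(1, 0, 0), sg, truth, seed = 1),
               "one entry per source")
  sg2 <- scan_gen_spec(grid_dims = c(6, 5, 4), n_sources = 2)
  expect_error(generate_scan(c(1, 0), sg2, truth, seed = 1), "grid")
})

test_that("two-Gaussian simulation matches its closed-form accuracy", {
  expect_error(simulate_two_gaussian_groups(1, 1), ">= 2")
  # indistinguishable groups sit at chance
  r0 <- simulate_two_gaussian_groups(20000, 0, seed = 1)
  expect_lt(abs(r0$accuracy - 50), 2)
  # large-sample accuracy approaches pnorm(delta / 2)
  r1 <- simulate_two_gaussian_groups(1e5, 1.0, seed = 2)
  expect_lt(abs(r1$accuracy - 100 * pnorm(0.5)), 0.6)
  # t statistic equals the standard pooled two-sample t (oracle: t.test)
  r2 <- simulate_two_gaussian_groups(50, 0.8, seed = 3)
  tt <- t.test(r2$samples$value[r2$samples$group == "B"],
               r2$samples$value[r2$samples$group == "A"],
               var.equal = TRUE)
  expect_equal(r2$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r2$df, 98L)
})
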