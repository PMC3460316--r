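test_that("counterbalanced folds partition 668 participants into 66/67", {
  tab <- generate_participants(training_cohort_spec(seed = 2))
  folds <- make_counterbalanced_folds(tab, k = 10, seed = 1)
  sizes <- tabulate(folds$fold, 10)
  expect_true(all(sizes %in% c(66L, 67L)))
  expect_equal(sum(sizes), 668)
  # disjoint and exhaustive by construction of the vector form
  expect_true(all(folds$fold >= 1 & folds$fold <= 10))
  expect_length(folds$fold, nrow(tab))
  expect_error(make_counterbalanced_folds(tab[1:5, ], k = 10), "more folds")
})

test_that("a perfectly balanced cohort divides with exact class balance", {
  tab <- data.frame(diagnosis = rep(c("control", "ADHD-C"), each = 50),
                    gender = "M", site = "x")
  folds <- make_counterbalanced_folds(tab, k = 10,
                                      strata = "diagnosis", seed = 3)
  for (i in 1:10) {
    sel <- tab$diagnosis[folds$fold == i]
    expect_equal(sum(sel == "control"), 5)
    expect_equal(sum(sel == "ADHD-C"), 5)
  }
})

test_that("greedy assignment beats the best of 1000 random assignments", {
  tab <- generate_participants(training_cohort_spec(seed = 4))
  folds <- make_counterbalanced_folds(tab, k = 10, seed = 5)
  cost_greedy <- fold_imbalance_cost(tab, folds$fold, 10)
  n <- nrow(tab)
  capacity <- rep(n %/% 10, 10) + (1:10 <= n %% 10)
  set.seed(5)
  cost_rand <- replicate(1000, {
    f <- sample(rep(1:10, capacity))
    fold_imbalance_cost(tab, f, 10)
  })
  expect_lte(cost_greedy, min(cost_rand))
})

test_that("classifier backends fit, predict and stay deterministic", {
  set.seed(6)
  n <- 60
  x <- rbind(matrix(stats::rnorm(n, -2, 0.5), ncol = 2),
             matrix(stats::rnorm(n, 2, 0.5), ncol = 2))
  y <- rep(c("control", "ADHD-C"), each = n / 2)
  for (fam in c("logistic", "linear-svm", "quadratic-svm", "cubic-svm",
                "rbf-svm")) {
    fit <- train_classifier(x, y, fam)
    expect_equal(mean(predict(fit, x) == y), 1)       # separable data
    fit2 <- train_classifier(x, y, fam)
    expect_identical(predict(fit2, x), predict(fit, x))
  }
  expect_error(train_classifier(x, rep("control", n), "logistic"),
               "single class")
})

test_that("the logistic boundary sits at the midpoint of symmetric groups", {
  set.seed(7)
  n <- 400
  x <- matrix(c(stats::rnorm(n, -1), stats::rnorm(n, 1)), ncol = 1)
  y <- rep(c("a", "b"), each = n)
  fit <- train_classifier(x, y, "logistic")
  grid <- matrix(seq(-0.5, 0.5, by = 0.01), ncol = 1)
  pred <- predict(fit, grid)
  boundary <- grid[max(which(pred == "a"))]
  expect_lt(abs(boundary), 0.15)
})

test_that("three-way prediction handles all classes", {
  set.seed(8)
  centers <- rbind(c(-3, 0), c(3, 0), c(0, 4))
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(stats::rnorm(80, 0, 0.4), ncol = 2), 2, centers[k, ], `+`)))
  y <- rep(c("control", "ADHD-C", "ADHD-I"), each = 40)
  fit <- train_classifier(x, y, "logistic")
  expect_gt(mean(predict(fit, x) == y), 0.95)
})

test_that("cross-validation keeps transforms train-fitted and reports both accuracies", {
  spec <- training_cohort_spec(seed = 9)
  spec$n_per_group <- c(control = 80L, `ADHD-C` = 40L, `ADHD-I` = 30L)
  tab <- generate_participants(spec)
  folds <- make_counterbalanced_folds(tab, k = 10, seed = 2)
  res <- cross_validate(tab, folds, pcd_builder(tab, "PCs1"),
                        task = "binary", family = "logistic")
  expect_length(res$test_accuracy, 10)
  expect_true(all(res$test_accuracy >= 0 & res$test_accuracy <= 100))
  expect_gte(res$mean_train, res$mean_test - 15)  # trained fit dominates
})

test_that("a memorizing feature set reaches perfect training accuracy", {
  set.seed(10)
  n <- 60
  tab <- data.frame(diagnosis = sample(c("control", "ADHD-C"), n, TRUE))
  folds <- make_counterbalanced_folds(tab, k = 10, strata = "diagnosis",
                                      seed = 1)
  # one indicator feature per participant: trivially separable in training
  idmat <- diag(n)
  builder <- function(train_idx, test_idx)
    list(train = idmat[train_idx, , drop = FALSE],
         test = idmat[test_idx, , drop = FALSE])
  res <- cross_validate(tab, folds, builder, task = "binary",
                        family = "cubic-svm")
  expect_equal(res$mean_train, 100)
  # but memorization cannot generalize: test accuracy is near chance
  expect_lt(res$mean_test, 80)
})

test_that("label-permuted cohorts score near chance under cross-validation", {
  spec <- training_cohort_spec(seed = 11)
  spec$n_per_group <- c(control = 60L, `ADHD-C` = 60L, `ADHD-I` = 0L)
  tab <- generate_participants(spec)
  set.seed(3)
  tab$diagnosis <- sample(tab$diagnosis)   # break any real structure
  folds <- make_counterbalanced_folds(tab, k = 10, seed = 4)
  res <- cross_validate(tab, folds, pcd_builder(tab, "PCs1"),
                        task = "binary", family = "logistic")
  expect_lt(abs(res$mean_test - 50), 15)
})

test_that("chance baseline reproduces the printed cohort baselines", {
  labels_train <- rep(c("control", "ADHD-C", "ADHD-I"), c(429, 141, 98))
  expect_equal(round(chance_baseline(labels_train), 1), 64.2)
  labels_hold <- rep(c("control", "ADHD-C", "ADHD-I"), c(94, 51, 26))
  expect_equal(round(chance_baseline(labels_hold), 1), 55.0)
  expect_equal(chance_baseline(rep("ADHD-I", 7)), 100)
  expect_error(chance_baseline(character(0)), "empty")
})

test_that("paired one-tailed t-test matches the closed form", {
  a <- c(70, 72, 68, 75, 71, 69, 74, 73, 70, 72)
  expect_equal(paired_onetailed_ttest(a, a),
               list(t = 0, df = 9L, p_value = 0.5))
  d <- c(2, 0, 1, 3, -1, 2, 1, 0, 2, 1)
  r <- paired_onetailed_ttest(a + d, a)
  oracle <- stats::t.test(d, alternative = "greater")
  expect_equal(r$t, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(r$p_value, oracle$p.value, tolerance = 1e-10)
  expect_equal(r$df, 9L)
  expect_warning(rz <- paired_onetailed_ttest(a + 1, a), "zero-variance")
  expect_equal(rz$p_value, 0)
  expect_error(paired_onetailed_ttest(a, a[1:5]), "differ")
})

test_that("competition scoring awards half points for wrong subtypes", {
  truth <- rep("control", 195)
  expect_equal(competition_score(truth, truth), 195)
  expect_equal(competition_score("ADHD-I", "ADHD-C"), 0.5)
  # 6 exact, 2 cross-subtype, 2 wrong -> 7 points
  tr <- c(rep("control", 4), "ADHD-C", "ADHD-I", "ADHD-C", "ADHD-I",
          "control", "control")
  pr <- c(rep("control", 4), "ADHD-C", "ADHD-I", "ADHD-I", "ADHD-C",
          "ADHD-C", "ADHD-I")
  expect_equal(competition_score(pr, tr), 7)
  expect_error(competition_score("healthy", "control"), "unknown label")
})

test_that("cohort group structure supports above-chance diagnosis in silico", {
  # gender/age/IQ shifts between groups carry real signal: the
  # personal-characteristic pipeline must beat the majority-class baseline
  tab <- generate_participants(training_cohort_spec(seed = 12))
  folds <- make_counterbalanced_folds(tab, k = 10, seed = 6)
  res <- cross_validate(tab, folds, pcd_builder(tab, "PCs2"),
                        task = "binary", family = "logistic")
  # paired one-tailed test against per-fold majority-class accuracy
  chance_test <- sapply(1:10, function(i) {
    lab <- collapse_binary(tab$diagnosis)[folds$fold == i]
    100 * mean(lab == "control")
  })
  pt <- paired_onetailed_ttest(res$test_accuracy, chance_test)
  expect_lt(pt$p_value, 0.05)
})
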