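diag_levels <- c("control", "ADHD-C", "ADHD-I")

#' Counterbalanced k-fold assignment
#'
#' Greedy stratified assignment: participants are processed in a seeded
#' random order and each is placed in the eligible fold (fold sizes may
#' differ by at most one) that minimizes the imbalance cost — the sum over
#' strata and categories of the absolute deviation of each fold's category
#' count from proportional allocation. Continuous strata (age, IQ) are
#' binned into terciles before costing. With n = 668 and k = 10 the folds
#' hold 66 or 67 participants each.
#'
#' @param table participant data.frame.
#' @param k number of folds.
#' @param strata character vector of table columns to balance (continuous
#'   columns are tercile-binned; defaults cover diagnosis, gender, age,
#'   handedness, IQ, medication and site).
#' @param seed integer seed.
#' @return object of class `fold_assignment` with `fold` (integer vector in
#'   table order), `k`, `strata`, `seed` and a per-stratum `balance` report.
#' @export
make_counterbalanced_folds <- function(table, k = 10L,
                                       strata = c("diagnosis", "gender",
                                                  "age", "handedness",
                                                  "full4_iq", "medication",
                                                  "site"),
                                       seed = 1L) {
  n <- nrow(table)
  if (k > n) stop("more folds than participants")
  strata <- intersect(strata, names(table))
  cat_strata <- lapply(strata, function(s) stratum_categories(table[[s]]))
  names(cat_strata) <- strata
  capacity <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  order_idx <- sample.int(n)
  fold <- integer(n)
  counts <- lapply(cat_strata, function(x) {
    lv <- sort(unique(x))
    matrix(0L, k, length(lv), dimnames = list(NULL, lv))
  })
  sizes <- integer(k)
  target_share <- 1 / k
  for (i in order_idx) {
    eligible <- which(sizes < capacity)
    costs <- vapply(eligible, function(f) {
      cost <- 0
      for (s in strata) {
        lv <- cat_strata[[s]][i]
        cnt <- counts[[s]]
        tot <- sum(cnt[, lv]) + 1L
        newcnt <- cnt[, lv]
        newcnt[f] <- newcnt[f] + 1L
        cost <- cost + sum(abs(newcnt - tot * target_share))
      }
      cost
    }, numeric(1))
    f <- eligible[which.min(costs)]        # tie -> lowest fold index
    fold[i] <- f
    sizes[f] <- sizes[f] + 1L
    for (s in strata)
      counts[[s]][f, cat_strata[[s]][i]] <-
        counts[[s]][f, cat_strata[[s]][i]] + 1L
  }
  structure(list(fold = fold, k = k, strata = strata, seed = seed,
                 balance = counts),
            class = "fold_assignment")
}

# Categorical view of one stratum: terciles for continuous columns (ties in
# the quantiles collapse bins), raw categories otherwise, NA as its own bin.
stratum_categories <- function(x) {
  if (is.numeric(x) && length(unique(stats::na.omit(x))) > 5L) {
    q <- unique(stats::quantile(x, c(1 / 3, 2 / 3), na.rm = TRUE))
    out <- as.character(cut(x, unique(c(-Inf, q, Inf))))
  } else out <- as.character(x)
  out[is.na(out)] <- "<missing>"
  out
}

#' Imbalance cost of an arbitrary fold assignment
#'
#' The documented cost minimized by [make_counterbalanced_folds()]: the sum
#' over strata, categories and folds of the absolute deviation from
#' proportional allocation. Useful as a baseline against random assignments.
#'
#' @param table participant data.frame.
#' @param fold integer fold vector.
#' @param k number of folds.
#' @param strata stratum columns (see [make_counterbalanced_folds()]).
#' @return non-negative numeric cost.
#' @export
fold_imbalance_cost <- function(table, fold, k,
                                strata = c("diagnosis", "gender", "age",
                                           "handedness", "full4_iq",
                                           "medication", "site")) {
  strata <- intersect(strata, names(table))
  cost <- 0
  for (s in strata) {
    x <- stratum_categories(table[[s]])
    for (lv in unique(x)) {
      cnt <- tabulate(fold[x == lv], k)
      cost <- cost + sum(abs(cnt - sum(cnt) / k))
    }
  }
  cost
}

#' Train a diagnostic classifier
#'
#' Thin, uniform interface over the five classifier families used by the
#' diagnostic pipelines: a (multinomial) logistic classifier with a small
#' ridge penalty, and linear / quadratic / cubic / radial-basis-function
#' support vector machines with complexity constant 1. Features are expected
#' already scaled to \[0, 1\]; the SVM backends are run without internal
#' rescaling so the pipeline's own scaling is authoritative.
#'
#' @param features numeric matrix (participants x features).
#' @param labels factor or character vector of class labels (>= 2 classes).
#' @param family one of `"logistic"`, `"linear-svm"`, `"quadratic-svm"`,
#'   `"cubic-svm"`, `"rbf-svm"`.
#' @param hyperparams optional list: `cost` (SVMs), `gamma` (RBF),
#'   `decay` (logistic ridge), `seed`.
#' @return object of class `diag_classifier` supporting [predict()].
#' @export
train_classifier <- function(features,
                             labels,
                             family = c("logistic", "linear-svm",
                                        "quadratic-svm", "cubic-svm",
                                        "rbf-svm"),
                             hyperparams = list()) {
  family <- match.arg(family)
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2L)
    stop("training labels contain a single class")
  labels <- droplevels(labels)
  cost <- hyperparams$cost %||% 1
  seed <- hyperparams$seed %||% 1L
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  features <- as.matrix(features)
  colnames(features) <- NULL
  fit <- switch(
    family,
    "logistic" = {
      decay <- hyperparams$decay %||% 1e-4
      df <- as.data.frame(features)
      names(df) <- paste0("f", seq_len(ncol(features)))
      df$.labels <- labels
      utils::capture.output(
        m <- nnet::multinom(.labels ~ ., decay = decay, maxit = 500,
                            MaxNWts = 100000, data = df))
      m
    },
    "linear-svm" = e1071::svm(features, labels, kernel = "linear",
                              cost = cost, scale = FALSE),
    "quadratic-svm" = e1071::svm(features, labels, kernel = "polynomial",
                                 degree = 2, coef0 = 1, cost = cost,
                                 scale = FALSE),
    "cubic-svm" = e1071::svm(features, labels, kernel = "polynomial",
                             degree = 3, coef0 = 1, cost = cost,
                             scale = FALSE),
    "rbf-svm" = e1071::svm(features, labels, kernel = "radial", cost = cost,
                           gamma = hyperparams$gamma %||%
                             (1 / ncol(features)), scale = FALSE))
  structure(list(fit = fit, family = family, levels = levels(labels)),
            class = "diag_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
predict.diag_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- NULL
  out <- if (object$family == "logistic") {
    df <- as.data.frame(newdata)
    names(df) <- paste0("f", seq_len(ncol(newdata)))
    predict(object$fit, newdata = df, type = "class")
  } else predict(object$fit, newdata)
  as.character(out)
}

#' Majority-class chance baseline
#'
#' Accuracy (in %) of guessing the most frequent class for every participant;
#' ties resolve in the order control < ADHD-C < ADHD-I.
#'
#' @param labels character/factor vector of diagnoses.
#' @return percentage in \[0, 100\].
#' @export
chance_baseline <- function(labels) {
  if (length(labels) == 0) stop("empty label vector")
  lv <- intersect(diag_levels, unique(as.character(labels)))
  if (length(lv) == 0) lv <- unique(as.character(labels))
  cnt <- vapply(lv, function(l) sum(labels == l), integer(1))
  100 * max(cnt) / length(labels)
}

#' Collapse three-way diagnosis labels for the binary task
#'
#' @param labels character/factor diagnoses.
#' @return character vector with both ADHD subtypes collapsed to `"ADHD"`.
#' @export
collapse_binary <- function(labels) {
  ifelse(as.character(labels) == "control", "control", "ADHD")
}

#' Cross-validate a diagnostic pipeline
#'
#' For each fold i, the feature builder is invoked with the training rows
#' (all folds but i) so every fitted transform — imputation, scaling, PCA
#' bases, statistical cluster selection — sees training data only; the
#' classifier is trained on those features and evaluated on both the held-out
#' fold (test accuracy) and its own training rows (training accuracy).
#'
#' @param table participant data.frame (provides the labels).
#' @param folds a [make_counterbalanced_folds()] result.
#' @param feature_builder `function(train_idx, test_idx)` returning
#'   `list(train = <matrix>, test = <matrix>)` with fitted transforms based
#'   on the training rows only. See [pcd_builder()].
#' @param task `"binary"` (controls vs ADHD, collapsing subtype) or
#'   `"threeway"`.
#' @param family,hyperparams classifier settings (see [train_classifier()]).
#' @return object of class `cv_result` with per-fold train/test accuracies
#'   (%), their means and standard deviations, and per-fold confusion
#'   matrices.
#' @export
cross_validate <- function(table, folds, feature_builder,
                           task = c("threeway", "binary"),
                           family = "logistic", hyperparams = list()) {
  task <- match.arg(task)
  labels <- as.character(table$diagnosis)
  if (task == "binary") labels <- collapse_binary(labels)
  k <- folds$k
  test_acc <- train_acc <- numeric(k)
  confusion <- vector("list", k)
  for (i in seq_len(k)) {
    test_idx <- which(folds$fold == i)
    train_idx <- which(folds$fold != i)
    feats <- feature_builder(train_idx, test_idx)
    model <- train_classifier(feats$train, labels[train_idx], family,
                              hyperparams)
    pred_test <- predict(model, feats$test)
    pred_train <- predict(model, feats$train)
    test_acc[i] <- 100 * mean(pred_test == labels[test_idx])
    train_acc[i] <- 100 * mean(pred_train == labels[train_idx])
    confusion[[i]] <- table(truth = labels[test_idx],
                            predicted = factor(pred_test,
                                               levels = unique(labels)))
  }
  structure(list(test_accuracy = test_acc, train_accuracy = train_acc,
                 mean_test = mean(test_acc), sd_test = stats::sd(test_acc),
                 mean_train = mean(train_acc),
                 sd_train = stats::sd(train_acc),
                 confusion = confusion, task = task, family = family),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s task, %s classifier\n", x$task, x$family))
  cat(sprintf("  test accuracy  %.1f +/- %.1f %%\n", x$mean_test, x$sd_test))
  cat(sprintf("  train accuracy %.1f +/- %.1f %%\n", x$mean_train,
              x$sd_train))
  invisible(x)
}

#' Personal-characteristic feature builder for cross-validation
#'
#' Returns a `feature_builder` closure for [cross_validate()] that selects,
#' recodes, imputes, encodes and scales the personal-characteristic features,
#' fitting all statistics on the training rows (or on all rows when
#' `global_stats = TRUE`, replicating whole-dataset fitting).
#'
#' @param table participant data.frame.
#' @param selection `"PCs1"` or `"PCs2"`.
#' @param global_stats fit imputation/scaling on all rows.
#' @return function(train_idx, test_idx) -> list(train, test).
#' @export
pcd_builder <- function(table, selection = "PCs1", global_stats = FALSE) {
  raw <- select_features(table, pcs_spec(selection))
  function(train_idx, test_idx) {
    fit_rows <- if (global_stats) seq_len(nrow(raw)) else train_idx
    stats <- fit_imputation(raw, fit_rows)
    full <- impute(raw, stats)
    scaled <- encode_and_scale(full, fit_rows = fit_rows)
    list(train = scaled[train_idx, , drop = FALSE],
         test = scaled[test_idx, , drop = FALSE])
  }
}

#' One-tailed paired t-test on fold accuracies
#'
#' Paired t on the 10 per-fold accuracy differences, df = 9, one-tailed in
#' the direction a > b. Identical vectors give t = 0, p = 0.5; a zero-sd
#' nonzero difference degenerates to p -> 0 (or 1) with a warning.
#'
#' @param acc_a,acc_b numeric vectors of per-fold accuracies, paired by fold.
#' @return list with `t`, `df`, `p_value`.
#' @export
paired_onetailed_ttest <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) stop("fold accuracy lengths differ")
  d <- acc_a - acc_b
  n <- length(d)
  df <- n - 1L
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (all(d == 0)) return(list(t = 0, df = df, p_value = 0.5))
    warning("zero-variance nonzero differences: p-value degenerates")
    return(list(t = sign(mean(d)) * Inf, df = df,
                p_value = if (mean(d) > 0) 0 else 1))
  }
  tval <- mean(d) / (sd_d / sqrt(n))
  list(t = tval, df = df, p_value = stats::pt(tval, df, lower.tail = FALSE))
}

#' Competition scoring rule
#'
#' One point per exact diagnosis; half a point for calling ADHD with the
#' wrong subtype; zero otherwise.
#'
#' @param predicted,truth character vectors over
#'   `control` / `ADHD-C` / `ADHD-I`.
#' @return total points (numeric).
#' @export
competition_score <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth)) stop("length mismatch")
  bad <- !(predicted %in% diag_levels) | !(truth %in% diag_levels)
  if (any(bad))
    stop("unknown label(s): ",
         paste(unique(c(predicted[bad], truth[bad])), collapse = ", "))
  exact <- predicted == truth
  adhd <- function(x) x %in% c("ADHD-C", "ADHD-I")
  half <- !exact & adhd(predicted) & adhd(truth)
  sum(exact) + 0.5 * sum(half)
}
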