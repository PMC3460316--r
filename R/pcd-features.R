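#' Personal-characteristic feature selections
#'
#' Two fixed selections of personal-characteristic fields are supported.
#' `PCs1` takes 7 features — site, gender, age, handedness, Verbal IQ,
#' Performance IQ, Full-4 IQ — and passes handedness through as a continuous
#' value. `PCs2` takes 9 features — adding the IQ-instrument indicator and the
#' Full-2 IQ — and recodes continuous Edinburgh handedness scores into the
#' 0/1 categorical scheme (see [recode_handedness()]).
#'
#' @param name `"PCs1"` or `"PCs2"`.
#' @return object of class `pcs_spec` with `fields`, `handedness_mode`, and
#'   the declared continuous/categorical typing of each field.
#' @export
pcs_spec <- function(name = c("PCs1", "PCs2")) {
  name <- match.arg(name)
  if (name == "PCs1") {
    fields <- c("site", "gender", "age", "handedness", "verbal_iq",
                "performance_iq", "full4_iq")
    categorical <- c("site", "gender")         # handedness stays continuous
    mode <- "as-is"
  } else {
    fields <- c("site", "gender", "age", "handedness", "iq_measure",
                "verbal_iq", "performance_iq", "full2_iq", "full4_iq")
    categorical <- c("site", "gender", "handedness", "iq_measure")
    mode <- "recode-edinburgh"
  }
  structure(list(name = name, fields = fields, categorical = categorical,
                 handedness_mode = mode),
            class = "pcs_spec")
}

#' Recode continuous Edinburgh handedness to the 0/1 scheme
#'
#' Positive scores become 1 (right-handed) and negative scores become 0
#' (left-handed). A score of exactly 0 — unspecified by the recoding rule —
#' maps to 1 with a warning. `NA` passes through.
#'
#' @param score numeric vector of Edinburgh scores in \[-100, 100\].
#' @return numeric vector of 0/1 (and `NA`).
#' @export
recode_handedness <- function(score) {
  if (!is.numeric(score)) stop("handedness scores must be numeric")
  if (any(!is.na(score) & score == 0))
    warning("Edinburgh score of exactly 0 recoded as 1 (right-handed)")
  out <- as.numeric(ifelse(score > 0, 1, ifelse(score < 0, 0, 1)))
  out[is.na(score)] <- NA_real_
  out
}

#' Select personal-characteristic features from a participant table
#'
#' Returns the raw (still incomplete) feature table in spec order. Under
#' `PCs2`, handedness values from the Edinburgh site are recoded to 0/1 and
#' handedness is treated as categorical; under `PCs1` it is the raw
#' continuous score. Categorical columns are returned as character so the
#' encoding step can one-hot them explicitly.
#'
#' @param table participant data.frame (see [generate_participants()]).
#' @param spec a [pcs_spec()].
#' @param edinburgh_site site whose handedness is a continuous Edinburgh
#'   score; defaults to the table's `"edinburgh_site"` attribute.
#' @return data.frame with `length(spec$fields)` columns, attribute
#'   `"categorical"` listing the categorical columns, and one row per
#'   participant in table order.
#' @export
select_features <- function(table, spec, edinburgh_site = NULL) {
  stopifnot(inherits(spec, "pcs_spec"))
  missing_cols <- setdiff(spec$fields, names(table))
  if (length(missing_cols))
    stop("participant table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(edinburgh_site)) edinburgh_site <- attr(table, "edinburgh_site")
  out <- table[, spec$fields, drop = FALSE]
  if (spec$handedness_mode == "recode-edinburgh" && nrow(out) > 0 &&
      !is.null(edinburgh_site) && !is.na(edinburgh_site)) {
    ed <- table$site == edinburgh_site
    if (any(ed)) out$handedness[ed] <- recode_handedness(out$handedness[ed])
  }
  for (f in spec$categorical) out[[f]] <- as.character(out[[f]])
  rownames(out) <- NULL
  attr(out, "categorical") <- spec$categorical
  attr(out, "selection") <- spec$name
  out
}

#' Fit imputation statistics on a participant subset
#'
#' Computes the mean of each continuous feature and the mode of each
#' categorical feature, ignoring missing values, on the rows in `fit_rows`
#' (by default all rows). During cross-validation pass the training-fold rows
#' so held-out participants never influence the statistics.
#'
#' @param features raw feature table from [select_features()].
#' @param fit_rows integer/logical index of rows to fit on.
#' @return object of class `imputation_stats`: named list of per-feature
#'   statistics plus the fitted-subset identifier.
#' @export
fit_imputation <- function(features, fit_rows = seq_len(nrow(features))) {
  categorical <- attr(features, "categorical")
  sub <- features[fit_rows, , drop = FALSE]
  stats_list <- lapply(names(features), function(f) {
    x <- sub[[f]]
    x <- x[!is.na(x)]
    if (f %in% categorical) {
      if (length(x) == 0) return(NA_character_)
      tb <- sort(table(x), decreasing = TRUE)
      names(tb)[1]                       # mode; ties broken alphabetically
    } else {
      if (length(x) == 0) return(0)      # all-missing column: neutral fill
      mean(x)
    }
  })
  names(stats_list) <- names(features)
  structure(list(stats = stats_list, categorical = categorical,
                 fit_rows = fit_rows),
            class = "imputation_stats")
}

#' Impute missing feature values
#'
#' Replaces every missing entry by the fitted mean (continuous) or mode
#' (categorical); observed entries are untouched.
#'
#' @param features raw feature table from [select_features()].
#' @param stats an [fit_imputation()] object covering every column.
#' @return complete feature table (no `NA` left).
#' @export
impute <- function(features, stats) {
  stopifnot(inherits(stats, "imputation_stats"))
  absent <- setdiff(names(features), names(stats$stats))
  if (length(absent))
    stop("imputation stats missing for: ", paste(absent, collapse = ", "))
  for (f in names(features)) {
    miss <- is.na(features[[f]])
    if (any(miss)) features[[f]][miss] <- stats$stats[[f]]
  }
  features
}

#' One-hot encode and min-max scale a complete feature table
#'
#' Categorical columns are expanded into one indicator column per observed
#' level (level sets and scaling bounds are fitted on `fit_rows`, or reused
#' from a previous `encoding` so that training-fold encodings can be applied
#' to held-out folds). Every resulting column is scaled to \[0, 1\] by its
#' fitted min/max; constant columns map to 0; values outside the fitted range
#' are clipped.
#'
#' @param features complete feature table (no `NA`).
#' @param fit_rows rows used to fit levels and bounds.
#' @param encoding optional encoding returned by a previous call, to be
#'   re-applied as-is.
#' @return numeric matrix with attribute `"encoding"` (levels and min/max per
#'   column) and descriptive column names.
#' @export
encode_and_scale <- function(features, fit_rows = seq_len(nrow(features)),
                             encoding = NULL) {
  categorical <- attr(features, "categorical")
  if (nrow(features) > 0 && anyNA(features)) stop("impute before encoding")
  if (is.null(encoding)) {
    fit <- features[fit_rows, , drop = FALSE]
    levels_by_col <- lapply(names(features), function(f)
      if (f %in% categorical) sort(unique(stats::na.omit(fit[[f]]))) else NULL)
    names(levels_by_col) <- names(features)
    encoding <- list(levels = levels_by_col, bounds = NULL,
                     categorical = categorical)
  }
  cols <- list()
  for (f in names(features)) {
    if (f %in% encoding$categorical) {
      lv <- encoding$levels[[f]]
      for (l in lv)
        cols[[paste0(f, "=", l)]] <- as.numeric(features[[f]] == l)
    } else {
      cols[[f]] <- as.numeric(features[[f]])
    }
  }
  m <- if (length(cols[[1]]) == 0 || nrow(features) == 0)
    matrix(numeric(0), nrow = 0, ncol = length(cols),
           dimnames = list(NULL, names(cols)))
  else do.call(cbind, cols)
  if (is.null(encoding$bounds)) {
    fitm <- m[fit_rows, , drop = FALSE]
    encoding$bounds <- list(
      min = if (nrow(fitm)) apply(fitm, 2, min) else rep(0, ncol(m)),
      max = if (nrow(fitm)) apply(fitm, 2, max) else rep(0, ncol(m)))
  }
  lo <- encoding$bounds$min; hi <- encoding$bounds$max
  rng <- hi - lo
  out <- m
  if (nrow(m)) {
    for (j in seq_len(ncol(m))) {
      out[, j] <- if (rng[j] > 0)
        pmin(1, pmax(0, (m[, j] - lo[j]) / rng[j]))
      else 0                              # constant column -> all zero
    }
  }
  attr(out, "encoding") <- encoding
  out
}

#' Invert min-max scaling for continuous columns
#'
#' @param scaled matrix from [encode_and_scale()].
#' @param column column name of a continuous feature.
#' @return original-scale values for that column.
#' @export
descale_column <- function(scaled, column) {
  enc <- attr(scaled, "encoding")
  lo <- enc$bounds$min[[column]]; hi <- enc$bounds$max[[column]]
  scaled[, column] * (hi - lo) + lo
}

#' Full personal-characteristic feature pipeline
#'
#' Select, recode, impute, one-hot encode and scale in one call. With
#' `global_stats = FALSE` (the default) imputation and scaling statistics are
#' fitted on `fit_rows` only, which keeps the transform leakage-safe inside
#' cross-validation; `global_stats = TRUE` replicates whole-dataset fitting.
#'
#' @param table participant data.frame.
#' @param selection `"PCs1"` or `"PCs2"`.
#' @param fit_rows rows used to fit the statistics (training fold).
#' @param global_stats fit on all rows regardless of `fit_rows`.
#' @return scaled numeric feature matrix (rows in table order) with the
#'   fitted encoding attached.
#' @export
pcd_feature_matrix <- function(table, selection = "PCs1",
                               fit_rows = seq_len(nrow(table)),
                               global_stats = FALSE) {
  if (global_stats) fit_rows <- seq_len(nrow(table))
  raw <- select_features(table, pcs_spec(selection))
  stats <- fit_imputation(raw, fit_rows)
  full <- impute(raw, stats)
  encode_and_scale(full, fit_rows = fit_rows)
}
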