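#' Specify a synthetic multi-site cohort
#'
#' A `cohort_spec` describes the marginal structure of a three-group
#' (control / ADHD-C / ADHD-I) multi-site cohort: group sizes, per-group site
#' distributions, age and IQ distributions, gender, handedness and medication
#' proportions, per-site IQ-battery availability, and optional extra per-site
#' per-field missingness. Fields are drawn independently given group and site;
#' joint structure (e.g. age-by-IQ correlation) is not modelled.
#'
#' @param n_per_group named integer vector with entries `control`, `ADHD-C`,
#'   `ADHD-I` (non-negative).
#' @param sites character vector of site names.
#' @param site_props group-by-site matrix of probabilities; each row must sum
#'   to 1 within 1e-9.
#' @param age_params group-by-2 matrix (columns `mean`, `sd`) in years.
#' @param gender_props per-group probability of female.
#' @param handedness_props group-by-4 matrix with columns
#'   `left`, `right`, `ambi`, `nodata`; rows sum to 1 within 1e-9. Categorical
#'   handedness is coded 0 = left, 1 = right, 2 = ambidextrous, `NA` = no data.
#' @param edinburgh_site name of the one site reporting continuous Edinburgh
#'   handedness scores (uniform on \[-100, 100\]), or `NA` for none.
#' @param iq_params list (one entry per group) of 4-by-2 matrices with rows
#'   `verbal_iq`, `performance_iq`, `full2_iq`, `full4_iq` and columns
#'   `mean`, `sd`; an `NA` mean marks a score never observed for that group.
#' @param iq_availability site-by-4 logical matrix saying which IQ scores each
#'   site provides (columns as in `iq_params` rows).
#' @param iq_measure_by_site named character vector giving each site's IQ
#'   instrument label (`NA` for sites without IQ testing).
#' @param medication_props group-by-3 matrix with columns `none`, `medicated`,
#'   `nodata`; rows sum to 1 within 1e-9.
#' @param missingness optional list keyed by site name; each entry is a named
#'   numeric vector of extra missing probabilities for table fields
#'   (e.g. `c(verbal_iq = 0.2)`). Probabilities must lie in \[0, 1\].
#' @param seed integer seed used by [generate_participants()].
#' @return validated object of class `cohort_spec`.
#' @seealso [training_cohort_spec()], [holdout_cohort_spec()]
#' @export
cohort_spec <- function(n_per_group, sites, site_props, age_params,
                        gender_props, handedness_props, edinburgh_site = NA,
                        iq_params, iq_availability, iq_measure_by_site,
                        medication_props, missingness = list(), seed = 1L) {
  groups <- c("control", "ADHD-C", "ADHD-I")
  n_per_group <- n_per_group[groups]
  if (any(is.na(n_per_group)) || any(n_per_group < 0))
    stop("`n_per_group` must give non-negative counts for control, ADHD-C, ADHD-I")
  stopifnot(is.character(sites), length(sites) >= 1L)
  check_prob_rows <- function(m, what) {
    if (any(m < -1e-12 | m > 1 + 1e-12))
      stop(sprintf("probabilities in %s must lie in [0, 1]", what))
    if (any(abs(rowSums(m) - 1) > 1e-9))
      stop(sprintf("rows of %s must sum to 1 (within 1e-9)", what))
  }
  site_props <- as.matrix(site_props)
  if (!all(dim(site_props) == c(3L, length(sites))))
    stop("`site_props` must be a 3 x n_sites matrix")
  check_prob_rows(site_props, "site_props")
  check_prob_rows(as.matrix(handedness_props), "handedness_props")
  check_prob_rows(as.matrix(medication_props), "medication_props")
  if (any(gender_props < 0 | gender_props > 1))
    stop("gender_props must lie in [0, 1]")
  for (s in names(missingness)) {
    p <- missingness[[s]]
    if (any(p < 0 | p > 1)) stop("missingness probabilities must lie in [0, 1]")
    if (!s %in% sites) stop(sprintf("missingness names unknown site '%s'", s))
  }
  if (!is.na(edinburgh_site) && !edinburgh_site %in% sites)
    stop("`edinburgh_site` must be one of `sites`")
  structure(list(n_per_group = n_per_group, sites = sites,
                 site_props = site_props, age_params = as.matrix(age_params),
                 gender_props = gender_props,
                 handedness_props = as.matrix(handedness_props),
                 edinburgh_site = edinburgh_site, iq_params = iq_params,
                 iq_availability = as.matrix(iq_availability),
                 iq_measure_by_site = iq_measure_by_site,
                 medication_props = as.matrix(medication_props),
                 missingness = missingness, seed = as.integer(seed)),
            class = "cohort_spec")
}

iq_fields <- c("verbal_iq", "performance_iq", "full2_iq", "full4_iq")

norm1 <- function(x) x / sum(x)

#' Default cohort specification mirroring the 668-participant training cohort
#'
#' Group sizes 429/141/98, per-group site mixes over seven active sites, age,
#' gender, handedness, medication and IQ-battery marginals as summarized for
#' the multi-site training cohort. One site reports continuous Edinburgh
#' handedness and provides no IQ scores. Printed percentages are renormalized
#' to sum exactly to one.
#'
#' @param seed integer seed.
#' @param missingness optional extra per-site per-field missingness.
#' @return a `cohort_spec`.
#' @export
training_cohort_spec <- function(seed = 1L, missingness = list()) {
  sites <- c("PekingU", "KKI", "NeuroIMAGE", "NYU", "OHSU", "UPitt", "WashU")
  site_props <- rbind(
    control  = norm1(c(27.0, 13.5,  5.1, 21.2,  8.4, 15.4, 9.3)),
    `ADHD-C` = norm1(c(20.6, 10.6, 11.3, 45.4, 12.1,  0.0, 0.0)),
    `ADHD-I` = norm1(c(50.0,  5.1,  0.0, 33.7, 11.2,  0.0, 0.0)))
  colnames(site_props) <- sites
  age_params <- rbind(control = c(12.4, 3.3), `ADHD-C` = c(11.4, 3.1),
                      `ADHD-I` = c(12.1, 2.5))
  colnames(age_params) <- c("mean", "sd")
  handed <- rbind(control  = norm1(c(2.6, 96.3, 0.2, 0.9)),
                  `ADHD-C` = norm1(c(3.5, 95.0, 0.0, 1.4)),
                  `ADHD-I` = norm1(c(2.0, 98.0, 0.0, 0.0)))
  colnames(handed) <- c("left", "right", "ambi", "nodata")
  med <- rbind(control  = norm1(c(67.4,  2.1, 30.5)),
               `ADHD-C` = norm1(c(34.0, 26.2, 39.7)),
               `ADHD-I` = norm1(c(60.2, 22.5, 17.4)))
  colnames(med) <- c("none", "medicated", "nodata")
  iq <- function(v, p, f2, f4) {
    m <- rbind(v, p, f2, f4); dimnames(m) <- list(iq_fields, c("mean", "sd")); m
  }
  iq_params <- list(
    control  = iq(c(114.9, 13.6), c(110.7, 13.5), c(112.2, 8.3), c(114.3, 13.3)),
    `ADHD-C` = iq(c(110.2, 16.1), c(103.3, 14.0), c(NA, NA), c(107.5, 13.9)),
    `ADHD-I` = iq(c(106.9, 15.2), c(100.6, 15.3), c(NA, NA), c(104.2, 14.1)))
  avail <- rbind(PekingU    = c(TRUE, TRUE, FALSE, TRUE),
                 KKI        = c(TRUE, TRUE, FALSE, TRUE),
                 NeuroIMAGE = c(FALSE, FALSE, FALSE, FALSE),
                 NYU        = c(TRUE, TRUE, FALSE, TRUE),
                 OHSU       = c(FALSE, FALSE, FALSE, TRUE),
                 UPitt      = c(TRUE, TRUE, TRUE, TRUE),
                 WashU      = c(FALSE, FALSE, FALSE, TRUE))
  colnames(avail) <- iq_fields
  iq_measure <- c(PekingU = "WISCC-R", KKI = "WISC-IV", NeuroIMAGE = NA,
                  NYU = "WASI", OHSU = "WASI", UPitt = "WASI",
                  WashU = "WASI-2sub")
  cohort_spec(n_per_group = c(control = 429L, `ADHD-C` = 141L, `ADHD-I` = 98L),
              sites = sites, site_props = site_props, age_params = age_params,
              gender_props = c(control = 0.476, `ADHD-C` = 0.170,
                               `ADHD-I` = 0.265),
              handedness_props = handed, edinburgh_site = "NeuroIMAGE",
              iq_params = iq_params, iq_availability = avail,
              iq_measure_by_site = iq_measure, medication_props = med,
              missingness = missingness, seed = seed)
}

#' Default cohort specification mirroring the 171-participant holdout cohort
#'
#' Group sizes 94/51/26 with the holdout cohort's site, age, gender,
#' handedness, medication and IQ marginals. The Edinburgh-handedness site
#' provides a two-subtest full-scale IQ for holdout participants.
#'
#' @inheritParams training_cohort_spec
#' @return a `cohort_spec`.
#' @export
holdout_cohort_spec <- function(seed = 1L, missingness = list()) {
  spec <- training_cohort_spec(seed = seed, missingness = missingness)
  sites <- spec$sites
  site_props <- rbind(
    control  = norm1(c(28.7, 8.5, 14.9, 12.8, 29.8,  5.3, 0.0)),
    `ADHD-C` = norm1(c(19.6, 5.9, 21.6, 43.1,  9.8,  0.0, 0.0)),
    `ADHD-I` = norm1(c(53.8, 0.0,  0.0, 26.9,  3.8, 15.4, 0.0)))
  colnames(site_props) <- sites
  age_params <- rbind(control = c(12.0, 4.2), `ADHD-C` = c(11.5, 3.5),
                      `ADHD-I` = c(12.1, 2.6))
  colnames(age_params) <- c("mean", "sd")
  handed <- rbind(control  = norm1(c(5.3, 93.6, 0.0, 1.1)),
                  `ADHD-C` = norm1(c(5.9, 92.2, 0.0, 2.0)),
                  `ADHD-I` = norm1(c(0.0, 100.0, 0.0, 0.0)))
  colnames(handed) <- c("left", "right", "ambi", "nodata")
  med <- rbind(control  = norm1(c(34.0,  0.0, 63.3)),
               `ADHD-C` = norm1(c( 3.9, 15.7, 80.4)),
               `ADHD-I` = norm1(c(46.2, 23.1, 30.8)))
  colnames(med) <- c("none", "medicated", "nodata")
  iq <- function(v, p, f2, f4) {
    m <- rbind(v, p, f2, f4); dimnames(m) <- list(iq_fields, c("mean", "sd")); m
  }
  iq_params <- list(
    control  = iq(c(119.2, 12.8), c(108.5, 13.6), c(100.6, 14.4), c(114.6, 12.3)),
    `ADHD-C` = iq(c(109.2, 13.6), c(101.1, 17.0), c(93.3, 16.5), c(107.0, 14.8)),
    `ADHD-I` = iq(c(108.6, 13.1), c(101.5, 11.2), c(NA, NA), c(106.1, 11.2)))
  avail <- spec$iq_availability
  avail["NeuroIMAGE", "full2_iq"] <- TRUE  # two-subtest IQ reported at holdout
  spec$iq_measure_by_site["NeuroIMAGE"] <- "WISC/WAIS-2sub"
  cohort_spec(n_per_group = c(control = 94L, `ADHD-C` = 51L, `ADHD-I` = 26L),
              sites = sites, site_props = site_props, age_params = age_params,
              gender_props = c(control = 0.511, `ADHD-C` = 0.157,
                               `ADHD-I` = 0.346),
              handedness_props = handed, edinburgh_site = "NeuroIMAGE",
              iq_params = iq_params, iq_availability = avail,
              iq_measure_by_site = spec$iq_measure_by_site,
              medication_props = med, missingness = missingness, seed = seed)
}

participant_columns <- c("participant_id", "diagnosis", "site", "age",
                         "gender", "handedness", "medication", "iq_measure",
                         iq_fields)

#' Generate a synthetic participant table
#'
#' Draws one row per participant from the marginal distributions in `spec`.
#' Categorical handedness is coded 0/1/2 (left/right/ambidextrous); rows from
#' the Edinburgh site carry continuous scores in \[-100, 100\]. IQ scores are
#' emitted only where the site provides the instrument and the group has a
#' stated distribution; all other entries, and entries hit by the extra
#' missingness probabilities, are `NA`.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `participant_id`, `diagnosis`, `site`,
#'   `age`, `gender`, `handedness`, `medication`, `iq_measure`, `verbal_iq`,
#'   `performance_iq`, `full2_iq`, `full4_iq`; the Edinburgh site name is
#'   attached as attribute `"edinburgh_site"`.
#' @export
generate_participants <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec")
  groups <- c("control", "ADHD-C", "ADHD-I")
  n_total <- sum(spec$n_per_group)
  tab <- data.frame(
    participant_id = character(0), diagnosis = character(0),
    site = character(0), age = numeric(0), gender = character(0),
    handedness = numeric(0), medication = character(0),
    iq_measure = character(0), verbal_iq = numeric(0),
    performance_iq = numeric(0), full2_iq = numeric(0), full4_iq = numeric(0),
    stringsAsFactors = FALSE)
  if (n_total > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$seed)
    rows <- vector("list", 3L)
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      n <- spec$n_per_group[[g]]
      if (n == 0) next
      site <- spec$sites[sample.int(length(spec$sites), n, replace = TRUE,
                                    prob = spec$site_props[g, ])]
      age <- stats::rnorm(n, spec$age_params[g, "mean"], spec$age_params[g, "sd"])
      gender <- ifelse(stats::runif(n) < spec$gender_props[[g]], "F", "M")
      hcat <- c(0, 1, 2, NA)[sample.int(4L, n, replace = TRUE,
                                        prob = spec$handedness_props[g, ])]
      handedness <- hcat
      edb <- !is.na(spec$edinburgh_site) & site == spec$edinburgh_site
      if (any(edb)) handedness[edb] <- stats::runif(sum(edb), -100, 100)
      medication <- c("none", "medicated", NA)[
        sample.int(3L, n, replace = TRUE, prob = spec$medication_props[g, ])]
      iqm <- unname(spec$iq_measure_by_site[site])
      iqs <- matrix(NA_real_, n, 4L, dimnames = list(NULL, iq_fields))
      for (f in iq_fields) {
        mu <- spec$iq_params[[g]][f, "mean"]
        sd <- spec$iq_params[[g]][f, "sd"]
        if (is.na(mu)) next
        ok <- spec$iq_availability[site, f]
        iqs[ok, f] <- stats::rnorm(sum(ok), mu, sd)
      }
      rows[[gi]] <- data.frame(
        participant_id = NA_character_, diagnosis = g, site = site, age = age,
        gender = gender, handedness = handedness, medication = medication,
        iq_measure = iqm, verbal_iq = iqs[, 1], performance_iq = iqs[, 2],
        full2_iq = iqs[, 3], full4_iq = iqs[, 4], stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    tab$participant_id <- sprintf("P%04d", seq_len(nrow(tab)))
    # extra per-site per-field missingness
    for (s in names(spec$missingness)) {
      p <- spec$missingness[[s]]
      for (f in names(p)) {
        if (!f %in% names(tab)) stop(sprintf("unknown field '%s' in missingness", f))
        hit <- tab$site == s & stats::runif(nrow(tab)) < p[[f]]
        tab[[f]][hit] <- NA
      }
    }
    rownames(tab) <- NULL
  }
  attr(tab, "edinburgh_site") <- spec$edinburgh_site
  tab
}

#' Write / read a participant table as CSV
#'
#' Missing entries are written as empty fields; the Edinburgh-site attribute
#' is stored in a header comment line.
#'
#' @param table participant data.frame from [generate_participants()].
#' @param path file path.
#' @return `read_participants` returns the data.frame with the
#'   `"edinburgh_site"` attribute restored.
#' @export
write_participants <- function(table, path) {
  ed <- attr(table, "edinburgh_site")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# edinburgh_site: %s",
                     if (is.null(ed) || is.na(ed)) "NA" else ed), con)
  utils::write.csv(table, con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_participants
#' @export
read_participants <- function(path) {
  first <- readLines(path, n = 1L)
  ed <- sub("^# edinburgh_site: ", "", first)
  tab <- utils::read.csv(path, comment.char = "#", na.strings = "",
                         stringsAsFactors = FALSE)
  attr(tab, "edinburgh_site") <- if (identical(ed, "NA")) NA else ed
  tab
}

# Save/restore the global RNG state so generators are seed-local.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
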