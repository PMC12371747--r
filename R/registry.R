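#' Registry cohort tables
#'
#' A cohort is a data frame with one row per patient and the columns of the
#' registry CSV interface: `patient_id`, `treatment_year`, `tumor_site`,
#' `prescribed_dose_gy`, `n_fractions`, `baseline_xerostomia`, per-gland
#' mean doses (`parotid_ipsi_mean`, `parotid_contra_mean`, `smg_ipsi_mean`,
#' `smg_contra_mean`, Gy), `dvh_file`, exclusion flags (`flag_adaptation`,
#' `flag_brachy`, `flag_reirradiation`), `glands_contoured`, and the
#' follow-up assessments as list columns `followup_times` (months since end
#' of radiotherapy) and `followup_grades` (RTOG/EORTC grade 0-4).
#'
#' @name cohort-table
NULL

tumor_sites <- function() {
  c("oropharynx", "nasopharynx", "hypopharynx", "larynx", "oral_cavity",
    "other")
}

baseline_categories <- function() c("none", "mild", "moderate_severe", "missing")

gland_columns <- function() {
  c("parotid_ipsi_mean", "parotid_contra_mean", "smg_ipsi_mean",
    "smg_contra_mean")
}

parse_num_list <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(v) {
    v <- trimws(v)
    if (length(v) == 0 || identical(v, "") || all(is.na(v))) return(numeric(0))
    as.numeric(v[nzchar(v)])
  })
}

join_num_list <- function(x) {
  vapply(x, function(v) paste(format(v, trim = TRUE, scientific = FALSE),
                              collapse = ";"), character(1))
}

#' Read a registry cohort CSV
#'
#' Parses the flat registry interface into a cohort data frame with
#' follow-up list columns (see [cohort-table]).
#'
#' @param path Path to the cohort CSV.
#' @return A cohort data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("cohort file not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "treatment_year", "tumor_site", "prescribed_dose_gy",
            "n_fractions", "baseline_xerostomia", gland_columns(),
            "flag_adaptation", "flag_brachy", "flag_reirradiation",
            "followup_times", "followup_grades")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    abort_data(sprintf("cohort file %s lacks columns: %s", path,
                       paste(missing_cols, collapse = ", ")))
  }
  tab$followup_times <- parse_num_list(tab$followup_times)
  tab$followup_grades <- lapply(parse_num_list(tab$followup_grades), as.integer)
  if (!"glands_contoured" %in% names(tab)) tab$glands_contoured <- TRUE
  if (!"dvh_file" %in% names(tab)) tab$dvh_file <- NA_character_
  for (fl in c("flag_adaptation", "flag_brachy", "flag_reirradiation",
               "glands_contoured")) {
    tab[[fl]] <- as.logical(tab[[fl]])
  }
  validate_cohort(tab)
  tab
}

#' Write a registry cohort CSV
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$followup_times <- join_num_list(out$followup_times)
  out$followup_grades <- join_num_list(out$followup_grades)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

validate_cohort <- function(cohort) {
  bad_site <- setdiff(unique(cohort$tumor_site), tumor_sites())
  if (length(bad_site) > 0) {
    ids <- cohort$patient_id[cohort$tumor_site %in% bad_site]
    abort_data(sprintf("unknown tumor site '%s' for record(s): %s",
                       paste(bad_site, collapse = ", "),
                       paste(utils::head(ids, 5), collapse = ", ")))
  }
  bad_base <- setdiff(unique(cohort$baseline_xerostomia),
                      baseline_categories())
  if (length(bad_base) > 0) {
    abort_data(sprintf("unknown baseline xerostomia category: %s",
                       paste(bad_base, collapse = ", ")))
  }
  if (any(cohort$prescribed_dose_gy <= 0)) {
    abort_data("prescribed doses must be > 0")
  }
  doses <- unlist(cohort[gland_columns()], use.names = FALSE)
  if (any(doses < 0, na.rm = TRUE)) abort_data("gland mean doses must be >= 0")
  grades <- unlist(cohort$followup_grades, use.names = FALSE)
  if (length(grades) > 0 && !all(grades %in% 0:4)) {
    abort_data("follow-up grades must be integers 0-4")
  }
  times <- unlist(cohort$followup_times, use.names = FALSE)
  if (length(times) > 0 && any(times <= 0)) {
    abort_data("follow-up times must be > 0 months")
  }
  invisible(cohort)
}

#' Inclusion criteria
#'
#' Configuration of the registry inclusion cascade: treatment-year range,
#' allowed tumor sites, gland contouring, minimum prescribed dose
#' (curative intent), an in-window follow-up requirement, and the three
#' treatment-based exclusions (plan adaptation, brachytherapy boost,
#' reirradiation).
#'
#' @param years Inclusive calendar-year range.
#' @param sites Allowed tumor sites.
#' @param min_dose Minimum prescribed dose in Gy.
#' @param followup_window Follow-up window in months; a patient needs at
#'   least one assessment inside it.
#' @param require_contoured Require salivary glands contoured.
#' @return A list of class `inclusion_criteria`.
#' @export
inclusion_criteria <- function(years = c(2012, 2024),
                               sites = tumor_sites(),
                               min_dose = 50,
                               followup_window = c(5, 24),
                               require_contoured = TRUE) {
  if (followup_window[1] >= followup_window[2]) {
    abort_config("followup_window must satisfy lo < hi")
  }
  structure(list(years = years, sites = sites, min_dose = min_dose,
                 followup_window = followup_window,
                 require_contoured = require_contoured),
            class = "inclusion_criteria")
}

#' Apply the inclusion/exclusion cascade
#'
#' Applies the criteria sequentially, attributing each excluded patient to
#' the first criterion they fail (so overlapping criteria are counted in
#' application order, as in exclusion flow charts). The order is: treatment
#' year, tumor site, glands contoured, prescribed dose, no in-window
#' follow-up, plan adaptation, brachytherapy boost, reirradiation.
#'
#' @param cohort A cohort data frame.
#' @param criteria An [inclusion_criteria()] object.
#' @return A list with `included` (cohort subset) and `tally` (an
#'   `exclusion_tally` data frame: criterion, n_excluded, plus attributes
#'   `n_input` and `n_remaining`).
#' @export
apply_inclusion <- function(cohort, criteria = inclusion_criteria()) {
  stopifnot(inherits(criteria, "inclusion_criteria"))
  validate_cohort(cohort)
  n_input <- nrow(cohort)
  win <- criteria$followup_window
  has_fu <- vapply(cohort$followup_times, function(tt) {
    any(tt >= win[1] & tt <= win[2])
  }, logical(1))

  checks <- list(
    year_out_of_range = cohort$treatment_year < criteria$years[1] |
      cohort$treatment_year > criteria$years[2],
    site_not_eligible = !(cohort$tumor_site %in% criteria$sites),
    glands_not_contoured = if (criteria$require_contoured)
      !cohort$glands_contoured else rep(FALSE, n_input),
    dose_below_curative = cohort$prescribed_dose_gy < criteria$min_dose,
    no_followup_in_window = !has_fu,
    plan_adaptation = cohort$flag_adaptation,
    brachy_boost = cohort$flag_brachy,
    reirradiation = cohort$flag_reirradiation)

  remaining <- rep(TRUE, n_input)
  counts <- integer(length(checks))
  names(counts) <- names(checks)
  for (i in seq_along(checks)) {
    hit <- remaining & checks[[i]]
    counts[i] <- sum(hit)
    remaining <- remaining & !hit
  }
  tally <- data.frame(criterion = names(counts),
                      n_excluded = unname(counts))
  attr(tally, "n_input") <- n_input
  attr(tally, "n_remaining") <- sum(remaining)
  class(tally) <- c("exclusion_tally", class(tally))
  list(included = cohort[remaining, , drop = FALSE], tally = tally)
}

#' @export
print.exclusion_tally <- function(x, ...) {
  cat(sprintf("Exclusion flow: %d records in, %d remaining\n",
              attr(x, "n_input"), attr(x, "n_remaining")))
  print.data.frame(x[x$n_excluded > 0, , drop = FALSE], row.names = FALSE)
  invisible(x)
}

#' Select the follow-up assessment nearest a target time
#'
#' Among follow-ups with time inside the window, returns the index of the
#' one minimising the distance to the target time; ties are broken toward
#' the earlier visit. Returns `NA` when no follow-up falls in the window.
#'
#' @param times Numeric vector of follow-up times in months.
#' @param target Target time in months (default 6, the assessment time of
#'   the model development cohort).
#' @param window Admissible window `c(lo, hi)` in months.
#' @return Integer index into `times`, or `NA_integer_`.
#' @export
#' @examples
#' select_followup(c(5, 8))    # 5 is nearer to 6 than 8
#' select_followup(c(4, 30))   # NA: both outside the window
select_followup <- function(times, target = 6, window = c(5, 24)) {
  if (window[1] >= window[2]) abort_config("window must satisfy lo < hi")
  ok <- which(times >= window[1] & times <= window[2])
  if (length(ok) == 0) return(NA_integer_)
  d <- abs(times[ok] - target)
  cand <- ok[d == min(d)]
  cand[which.min(times[cand])]
}

#' Binary endpoint from a follow-up grade
#'
#' Late xerostomia of grade >= 2 (moderate-to-severe) on the RTOG/EORTC
#' morbidity scale.
#'
#' @param grade Integer grade(s) 0-4.
#' @return Integer 0/1 vector.
#' @export
derive_endpoint <- function(grade) {
  if (!all(grade %in% 0:4)) abort_data("grades must be integers 0-4")
  as.integer(grade >= 2)
}

#' Selected follow-up and endpoint per patient
#'
#' Applies [select_followup()] and [derive_endpoint()] to every record.
#'
#' @param cohort A cohort data frame.
#' @param target,window Passed to [select_followup()].
#' @return Data frame with `followup_time`, `followup_grade`, `outcome`
#'   (NA where no in-window follow-up exists).
#' @export
cohort_endpoints <- function(cohort, target = 6, window = c(5, 24)) {
  idx <- mapply(function(tt, gg) select_followup(tt, target, window),
                cohort$followup_times, cohort$followup_grades)
  time <- rep(NA_real_, nrow(cohort))
  grade <- rep(NA_integer_, nrow(cohort))
  has <- !is.na(idx)
  time[has] <- mapply(function(tt, i) tt[i], cohort$followup_times[has],
                      idx[has])
  grade[has] <- mapply(function(gg, i) gg[i], cohort$followup_grades[has],
                       idx[has])
  out <- rep(NA_integer_, nrow(cohort))
  out[has] <- derive_endpoint(grade[has])
  data.frame(followup_time = time, followup_grade = grade, outcome = out)
}

fmt_pct <- function(k, n) round(100 * k / n)

#' Cohort summary table
#'
#' Counts and percentages for categorical variables, medians and
#' interquartile ranges for per-gland mean doses, outcome prevalence and
#' follow-up summary, in the style of a patient-characteristics table.
#'
#' @param cohort A cohort data frame (included patients).
#' @param target,window Follow-up selection settings.
#' @return A list of class `cohort_summary`.
#' @export
cohort_summary <- function(cohort, target = 6, window = c(5, 24)) {
  if (nrow(cohort) == 0) abort_domain("cannot summarise an empty cohort")
  ep <- cohort_endpoints(cohort, target, window)
  n <- nrow(cohort)
  n_events <- sum(ep$outcome, na.rm = TRUE)
  site_tab <- table(factor(cohort$tumor_site, levels = tumor_sites()))
  base_tab <- table(factor(cohort$baseline_xerostomia,
                           levels = baseline_categories()))
  doses <- lapply(cohort[gland_columns()], function(d) {
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    c(q25 = q[1], median = q[2], q75 = q[3])
  })
  structure(
    list(n = n,
         n_events = n_events,
         prevalence = n_events / n,
         prevalence_percent = fmt_pct(n_events, n),
         prevalence_percent_1dp = round(100 * n_events / n, 1),
         tumor_site = data.frame(site = names(site_tab),
                                 n = as.integer(site_tab),
                                 percent = fmt_pct(as.integer(site_tab), n)),
         baseline = data.frame(category = names(base_tab),
                               n = as.integer(base_tab),
                               percent = fmt_pct(as.integer(base_tab), n)),
         gland_doses = doses,
         followup_median = stats::median(ep$followup_time, na.rm = TRUE),
         followup_range = range(ep$followup_time, na.rm = TRUE)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: n = %d, events = %d (%d%%; %.1f%%)\n",
              x$n, x$n_events, x$prevalence_percent,
              x$prevalence_percent_1dp))
  cat(sprintf("Follow-up: median %.1f months (range %.0f-%.0f)\n",
              x$followup_median, x$followup_range[1], x$followup_range[2]))
  cat("Median gland mean dose in Gy (IQR):\n")
  for (g in names(x$gland_doses)) {
    q <- x$gland_doses[[g]]
    cat(sprintf("  %-20s %.1f (%.1f-%.1f)\n", g, q["median"], q["q25"],
                q["q75"]))
  }
  invisible(x)
}

#' Published reference cohort summaries
#'
#' Combined-gland median physical mean doses (Gy) and headline counts of
#' the validation registry cohort and of the model development cohort, for
#' side-by-side comparison of dose levels between cohorts.
#'
#' @return A list with elements `validation` and `development`, each with
#'   `parotid_median`, `smg_median`, `n`, `n_events`.
#' @export
lipp_reference <- function() {
  list(validation = list(parotid_median = 22.6, smg_median = 54.8,
                         n = 674, n_events = 204),
       development = list(parotid_median = 25.6, smg_median = 56.6,
                          n = 1145, n_events = 531))
}

merge_sparse_categories <- function(a, b, min_expected = 1) {
  # merge categories whose expected count is below threshold into the
  # largest remaining category, to keep the chi-square approximation usable
  tot <- a + b
  keep <- tot > 0
  a <- a[keep]; b <- b[keep]
  n <- sum(a) + sum(b)
  expected_min <- pmin(sum(a) * (a + b) / n, sum(b) * (a + b) / n)
  if (any(expected_min < min_expected) && length(a) > 2) {
    small <- expected_min < min_expected
    merged_a <- c(a[!small], merged = sum(a[small]))
    merged_b <- c(b[!small], merged = sum(b[small]))
    warning("merged sparse categories before chi-square test",
            call. = FALSE)
    return(list(a = merged_a, b = merged_b))
  }
  list(a = a, b = b)
}

#' Compare two cohorts variable by variable
#'
#' Categorical variables are compared with an (uncorrected) Pearson
#' chi-square test on their count tables; continuous variables with a
#' two-sample Welch t-test, either from raw values or from summary
#' `(mean, sd, n)` triplets. Categories with near-zero expected counts are
#' merged with a warning.
#'
#' @param a,b Named lists with elements `categorical` (named list of count
#'   vectors over identical category sets) and `continuous` (named list of
#'   either raw numeric vectors or `list(mean =, sd =, n =)`).
#' @param alpha Significance threshold for the `significant` flag.
#' @return Data frame with columns `variable`, `type`, `statistic`,
#'   `p_value`, `significant`.
#' @export
#' @examples
#' cohort_compare(
#'   a = list(categorical = list(sex = c(male = 481, female = 193))),
#'   b = list(categorical = list(sex = c(male = 850, female = 295))))
cohort_compare <- function(a, b, alpha = 0.05) {
  rows <- list()
  cats <- union(names(a$categorical), names(b$categorical))
  for (v in cats) {
    ca <- a$categorical[[v]]; cb <- b$categorical[[v]]
    if (is.null(ca) || is.null(cb) || !identical(names(ca), names(cb))) {
      abort_data(sprintf("categorical variable '%s' must be present in both cohorts with matching categories", v))
    }
    m <- merge_sparse_categories(ca, cb)
    tab <- rbind(m$a, m$b)
    tst <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "categorical",
      statistic = unname(tst$statistic), p_value = unname(tst$p.value))
  }
  conts <- union(names(a$continuous), names(b$continuous))
  for (v in conts) {
    xa <- a$continuous[[v]]; xb <- b$continuous[[v]]
    if (is.null(xa) || is.null(xb)) {
      abort_data(sprintf("continuous variable '%s' missing in one cohort", v))
    }
    if (is.list(xa) || is.list(xb)) {
      sa <- summary_stats(xa); sb <- summary_stats(xb)
      tt <- welch_from_summary(sa, sb)
    } else {
      ht <- stats::t.test(xa, xb)
      tt <- c(statistic = unname(ht$statistic), p_value = ht$p.value)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "continuous",
      statistic = unname(tt["statistic"]), p_value = unname(tt["p_value"]))
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}

summary_stats <- function(x) {
  if (is.list(x)) {
    stopifnot(all(c("mean", "sd", "n") %in% names(x)))
    return(list(mean = x$mean, sd = x$sd, n = x$n))
  }
  list(mean = mean(x), sd = stats::sd(x), n = length(x))
}

welch_from_summary <- function(sa, sb) {
  se2a <- sa$sd^2 / sa$n
  se2b <- sb$sd^2 / sb$n
  t_stat <- (sa$mean - sb$mean) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 /
    (se2a^2 / (sa$n - 1) + se2b^2 / (sb$n - 1))
  c(statistic = t_stat, p_value = 2 * stats::pt(-abs(t_stat), df))
}
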