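#' Fit a log-normal distribution to a median and IQR
#'
#' Two-parameter fit minimising the squared quantile error between the
#' log-normal (q25, median, q75) and the targets. When the targets are
#' symmetric on the log scale the match is exact and the residual is 0;
#' published dose summaries are never far from that.
#'
#' @param median,q25,q75 Target quantiles, `0 < q25 < median < q75`.
#' @return List with `meanlog`, `sdlog`, `residual` (sum of squared
#'   quantile errors at the optimum).
#' @export
calibrate_lognormal <- function(median, q25, q75) {
  if (!(0 < q25 && q25 < median && median < q75)) {
    abort_config("quantile targets must satisfy 0 < q25 < median < q75")
  }
  targets <- c(q25, median, q75)
  obj <- function(par) {
    q <- stats::qlnorm(c(0.25, 0.5, 0.75), par[1], exp(par[2]))
    sum((q - targets)^2)
  }
  start <- c(log(median), log((log(q75) - log(q25)) / (2 * stats::qnorm(0.75))))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  list(meanlog = fit$par[1], sdlog = exp(fit$par[2]), residual = fit$value)
}

#' Per-gland dose distribution targets of the validation registry
#'
#' Median and interquartile range (Gy) of the physical mean dose to each
#' salivary gland in the registry cohort the generator emulates.
#'
#' @return Data frame with columns `gland`, `median`, `q25`, `q75`.
#' @export
table1_dose_targets <- function() {
  data.frame(
    gland = c("parotid_ipsi", "parotid_contra", "smg_ipsi", "smg_contra"),
    median = c(28.3, 16.2, 65.2, 46.2),
    q25 = c(22.4, 11.0, 59.0, 39.6),
    q75 = c(37.9, 19.6, 67.6, 51.7))
}

#' Synthetic cohort generator configuration
#'
#' Defines the study conditions the generator emulates: registry size and
#' exclusion-flag counts, per-gland dose distributions matching the
#' published medians/IQRs, inter-gland correlation, the baseline
#' xerostomia distribution, the follow-up time distribution, and the true
#' outcome model with optional miscalibration knobs.
#'
#' @param n Number of included patients (after exclusions).
#' @param seed Integer seed for reproducibility (`NULL` uses the current
#'   RNG stream).
#' @param dose_targets Data frame as [table1_dose_targets()].
#' @param rho Inter-gland Gaussian-copula correlation (a sensitivity knob,
#'   not an estimate; the source registry publishes no joint information).
#' @param baseline_probs Category probabilities among patients with a
#'   recorded baseline (`none`, `mild`, `moderate_severe`).
#' @param baseline_recorded Fraction of patients with any recorded
#'   baseline assessment; the rest are `missing`.
#' @param true_model `ntcp_model` generating the outcomes; default
#'   [synthetic_true_model()], the LIPP dose response with the intercept
#'   calibrated to `prevalence_target`.
#' @param delta_a,delta_b Miscalibration knobs: outcomes are drawn from
#'   `plogis(delta_a + delta_b * lp_true)`. Neutral at (0, 1).
#' @param followup_window Follow-up times are generated inside this window
#'   (months).
#' @param followup_median Target median follow-up time in months.
#' @param exclusion_counts Named counts of disjoint exclusion flags
#'   assigned to extra records beyond `n` (`plan_adaptation`,
#'   `brachy_boost`, `reirradiation`).
#' @param prevalence_target Expected outcome prevalence used when
#'   calibrating the default true model's intercept.
#' @param dose_cap Upper plausibility bound (Gy) at which sampled mean
#'   doses are truncated.
#' @param smg_combination How the true model combines the two
#'   submandibular glands: `"mean"` (equal-weight mean) or `"sum"`.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 674, seed = NULL,
                          dose_targets = table1_dose_targets(),
                          rho = 0.4,
                          baseline_probs = c(none = 0.83, mild = 0.16,
                                             moderate_severe = 0.01),
                          baseline_recorded = 0.15,
                          true_model = NULL,
                          delta_a = 0, delta_b = 1,
                          followup_window = c(5, 24),
                          followup_median = 10.3,
                          exclusion_counts = c(plan_adaptation = 61,
                                               brachy_boost = 34,
                                               reirradiation = 71),
                          prevalence_target = 0.30,
                          dose_cap = 90,
                          smg_combination = c("mean", "sum")) {
  if (n <= 0) abort_config("n must be positive")
  if (abs(sum(baseline_probs) - 1) > 1e-9) {
    abort_config("baseline_probs must sum to 1")
  }
  if (rho < 0 || rho >= 1) abort_config("rho must lie in [0, 1)")
  if (followup_window[1] >= followup_window[2]) {
    abort_config("followup_window must satisfy lo < hi")
  }
  structure(
    list(n = n, seed = seed, dose_targets = dose_targets, rho = rho,
         baseline_probs = baseline_probs,
         baseline_recorded = baseline_recorded,
         true_model = true_model, delta_a = delta_a, delta_b = delta_b,
         followup_window = followup_window,
         followup_median = followup_median,
         exclusion_counts = exclusion_counts,
         prevalence_target = prevalence_target,
         dose_cap = dose_cap,
         smg_combination = match.arg(smg_combination)),
    class = "cohort_config")
}

#' Read a generator configuration from YAML
#'
#' @param path YAML file whose keys are arguments of [cohort_config()].
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
  x <- yaml::read_yaml(path)
  if (!is.null(x$dose_targets)) {
    x$dose_targets <- as.data.frame(x$dose_targets)
  }
  for (nm in c("baseline_probs", "exclusion_counts")) {
    if (!is.null(x[[nm]])) x[[nm]] <- unlist(x[[nm]])
  }
  for (nm in c("followup_window")) {
    if (!is.null(x[[nm]])) x[[nm]] <- as.numeric(unlist(x[[nm]]))
  }
  do.call(cohort_config, x)
}

gland_dose_params <- function(config) {
  tg <- config$dose_targets
  params <- lapply(seq_len(nrow(tg)), function(i) {
    calibrate_lognormal(tg$median[i], tg$q25[i], tg$q75[i])
  })
  names(params) <- tg$gland
  params
}

draw_gland_doses <- function(n, config) {
  params <- gland_dose_params(config)
  k <- length(params)
  sigma <- matrix(config$rho, k, k)
  diag(sigma) <- 1
  z <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = sigma)
  if (n == 1) z <- matrix(z, nrow = 1)
  u <- stats::pnorm(z)
  d <- vapply(seq_len(k), function(j) {
    pmin(stats::qlnorm(u[, j], params[[j]]$meanlog, params[[j]]$sdlog),
         config$dose_cap)
  }, numeric(n))
  colnames(d) <- paste0(names(params), "_mean")
  as.data.frame(d)
}

draw_baseline <- function(n, config) {
  recorded <- stats::runif(n) < config$baseline_recorded
  cat <- rep("missing", n)
  k <- sum(recorded)
  if (k > 0) {
    cat[recorded] <- sample(names(config$baseline_probs), k, replace = TRUE,
                            prob = config$baseline_probs)
  }
  cat
}

smg_combined <- function(smg_ipsi, smg_contra, combination = "mean") {
  switch(combination,
         mean = (smg_ipsi + smg_contra) / 2,
         sum = smg_ipsi + smg_contra,
         abort_config(sprintf("unknown smg_combination '%s'", combination)))
}

features_from_doses <- function(doses, baseline, combination = "mean") {
  data.frame(
    parotid_sum = doses$parotid_ipsi_mean + doses$parotid_contra_mean,
    smg = smg_combined(doses$smg_ipsi_mean, doses$smg_contra_mean,
                       combination),
    baseline = ifelse(baseline == "missing", "none", baseline))
}

#' Default true model of the synthetic registry
#'
#' Keeps the LIPP dose coefficients (hence the published dose-response
#' shape) and solves for the intercept such that the expected outcome
#' prevalence under the configured dose marginals equals
#' `config$prevalence_target`. The calibration uses a fixed internal
#' Monte-Carlo sample, so the returned model is deterministic for a given
#' configuration and independent of the caller's RNG state.
#'
#' @param config A [cohort_config()].
#' @param n_mc Monte-Carlo sample size for the intercept calibration.
#' @return An `ntcp_model`.
#' @export
synthetic_true_model <- function(config = cohort_config(), n_mc = 2e5) {
  base <- lipp_model()
  lp_rest <- with_preserved_seed(104729, {
    doses <- draw_gland_doses(n_mc, config)
    baseline <- draw_baseline(n_mc, config)
    feats <- features_from_doses(doses, baseline, config$smg_combination)
    linear_predictor(base, feats) - base$intercept
  })
  root <- stats::uniroot(
    function(a) mean(stats::plogis(a + lp_rest)) - config$prevalence_target,
    interval = c(-30, 10), tol = 1e-10)
  ntcp_model(root$root, base$coef_parotid, base$coef_smg,
             baseline_scores = base$baseline_scores,
             dose_transform = base$dose_transform,
             provenance = sprintf(
               "synthetic registry true model (LIPP dose response, intercept calibrated to prevalence %.2f)",
               config$prevalence_target))
}

solve_followup_beta <- function(config) {
  win <- config$followup_window
  med <- min(max(config$followup_median, win[1] + 0.1), win[2] - 0.1)
  frac <- (med - win[1]) / (win[2] - win[1])
  shape1 <- 2
  root <- stats::uniroot(
    function(s2) stats::qbeta(0.5, shape1, s2) - frac,
    interval = c(0.05, 200), tol = 1e-10)
  c(shape1 = shape1, shape2 = root$root)
}

# The primary (outcome-carrying) assessment time follows the calibrated
# Beta distribution; any additional assessments are placed strictly
# farther from the 6-month target so the nearest-to-6 selection always
# returns the primary time and the selected-follow-up median matches the
# configured target.
draw_followups <- function(n, config) {
  shp <- solve_followup_beta(config)
  win <- config$followup_window
  target <- 6
  n_fu <- sample(1:3, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  t0 <- round(win[1] + (win[2] - win[1]) *
                stats::rbeta(n, shp["shape1"], shp["shape2"]), 1)
  t0 <- pmin(pmax(t0, win[1]), win[2])
  lapply(seq_len(n), function(i) {
    times <- t0[i]
    lower <- target + abs(t0[i] - target) + 0.5
    k_extra <- n_fu[i] - 1L
    if (k_extra > 0 && lower < win[2] - 0.2) {
      extra <- round(stats::runif(k_extra, lower, win[2]), 1)
      times <- c(times, extra)
    }
    sort(unique(times))
  })
}

grade_for_outcome <- function(y) {
  if (y == 1) sample(c(2L, 3L), 1, prob = c(0.85, 0.15))
  else sample(c(0L, 1L), 1, prob = c(0.6, 0.4))
}

#' Generate a synthetic registry cohort
#'
#' Draws a registry-like pool of patient records with the statistical
#' structure of the emulated validation registry: per-gland mean doses
#' from correlated truncated log-normal marginals matching the published
#' median/IQR targets, treatment years and tumor sites with the published
#' mix, mostly 68 Gy / 34 fraction prescriptions, a sparse recorded
#' baseline, follow-up times on the configured window, binary outcomes
#' drawn from `plogis(delta_a + delta_b * lp_true)`, follow-up grades
#' consistent with the drawn outcome at the selected assessment, and
#' disjoint exclusion flags on extra records beyond the target cohort
#' size.
#'
#' @param config A [cohort_config()].
#' @return A cohort data frame (see [cohort-table]) of
#'   `config$n + sum(config$exclusion_counts)` records, with attributes
#'   `true_model`, `lp_true`, `p_true` and `config`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n = 50, seed = 1))
#' nrow(apply_inclusion(coh)$included)
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  runner <- function() generate_cohort_impl(config)
  if (is.null(config$seed)) runner() else
    with_preserved_seed(config$seed, runner())
}

generate_cohort_impl <- function(config) {
  n_extra <- sum(config$exclusion_counts)
  n_pool <- config$n + n_extra
  true_model <- config$true_model
  if (is.null(true_model)) true_model <- synthetic_true_model(config)

  doses <- draw_gland_doses(n_pool, config)
  baseline <- draw_baseline(n_pool, config)
  feats <- features_from_doses(doses, baseline, config$smg_combination)
  lp <- linear_predictor(true_model, feats)
  p_true <- stats::plogis(config$delta_a + config$delta_b * lp)
  y <- stats::rbinom(n_pool, 1, p_true)

  # treatment era mix: 16% 2012-2016, 36% 2017-2019, 48% 2020-2024
  era <- sample(1:3, n_pool, replace = TRUE, prob = c(0.16, 0.36, 0.48))
  year <- ifelse(era == 1, sample(2012:2016, n_pool, replace = TRUE),
          ifelse(era == 2, sample(2017:2019, n_pool, replace = TRUE),
                 sample(2020:2024, n_pool, replace = TRUE)))
  site <- sample(tumor_sites(), n_pool, replace = TRUE,
                 prob = c(509, 20, 33, 35, 29, 48) / 674)
  sched <- sample(1:3, n_pool, replace = TRUE,
                  prob = c(0.037, 0.88, 0.083))
  dose_rx <- c(60, 68, 74.8)[sched]
  n_fx <- c(30L, 34L, 34L)[sched]

  fu_times <- draw_followups(n_pool, config)
  fu_grades <- vector("list", n_pool)
  for (i in seq_len(n_pool)) {
    k <- length(fu_times[[i]])
    fu_grades[[i]] <- vapply(seq_len(k), function(j) grade_for_outcome(y[i]),
                             integer(1))
  }

  flags <- data.frame(flag_adaptation = rep(FALSE, n_pool),
                      flag_brachy = rep(FALSE, n_pool),
                      flag_reirradiation = rep(FALSE, n_pool))
  if (n_extra > 0) {
    at <- config$n
    cnt <- config$exclusion_counts
    nm <- c(plan_adaptation = "flag_adaptation",
            brachy_boost = "flag_brachy",
            reirradiation = "flag_reirradiation")
    for (crit in names(cnt)) {
      if (cnt[[crit]] > 0) {
        flags[at + seq_len(cnt[[crit]]), nm[[crit]]] <- TRUE
        at <- at + cnt[[crit]]
      }
    }
  }

  cohort <- data.frame(
    patient_id = sprintf("S%05d", seq_len(n_pool)),
    treatment_year = year,
    tumor_site = site,
    prescribed_dose_gy = dose_rx,
    n_fractions = n_fx,
    baseline_xerostomia = baseline,
    stringsAsFactors = FALSE)
  cohort <- cbind(cohort, doses)
  cohort$dvh_file <- NA_character_
  cohort <- cbind(cohort, flags)
  cohort$glands_contoured <- TRUE
  cohort$followup_times <- fu_times
  cohort$followup_grades <- fu_grades

  perm <- sample(n_pool)
  cohort <- cohort[perm, , drop = FALSE]
  rownames(cohort) <- NULL
  attr(cohort, "true_model") <- true_model
  attr(cohort, "lp_true") <- lp[perm]
  attr(cohort, "p_true") <- p_true[perm]
  attr(cohort, "config") <- config
  cohort
}

#' Construct a synthetic DVH with an exact mean dose
#'
#' Builds a valid cumulative DVH whose [mean_dose()] equals `target_mean`
#' to within 1e-6 Gy: a smooth differential shape centred on the target is
#' moment-matched, then the dose axis is rescaled exactly (mean dose is
#' linear under dose scaling).
#'
#' @param target_mean Target mean dose in Gy (>= 0).
#' @param n_bins Number of dose bins.
#' @param spread Relative width of the differential dose distribution
#'   (> 0).
#' @param structure Structure label.
#' @param volume_cc Optional absolute volume.
#' @return A [dvh()] object.
#' @export
generate_dvh <- function(target_mean, n_bins = 50, spread = 0.25,
                         structure = "other", volume_cc = NA_real_) {
  if (target_mean < 0) abort_config("target_mean must be >= 0")
  if (spread <= 0) abort_config("spread must be > 0")
  if (target_mean == 0) {
    return(dvh(structure, c(0, 1e-7), c(1, 0), volume_cc))
  }
  edges <- seq(0, 2.5 * target_mean, length.out = n_bins + 1)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  w <- stats::dnorm(mid, mean = target_mean, sd = spread * target_mean)
  if (sum(w) <= 0) abort_config("spread incompatible with a valid shape")
  w <- w / sum(w)
  m0 <- sum(mid * w)
  edges <- edges * (target_mean / m0)
  cum <- c(1, 1 - cumsum(w))
  cum[length(cum)] <- 0
  dvh(structure, edges, pmin(pmax(cum, 0), 1), volume_cc)
}

#' Write a synthetic registry to disk
#'
#' Emits the registry cohort CSV and, optionally, per-patient DVH files
#' reconstructed from the per-gland mean doses (each DVH reproduces its
#' gland's mean dose to within 1e-6 Gy).
#'
#' @param cohort A cohort data frame.
#' @param dir Output directory (created if needed).
#' @param write_dvhs Also write per-patient DVH CSVs and fill `dvh_file`.
#' @param n_bins Bins per synthetic DVH.
#' @return Path of the cohort CSV, invisibly.
#' @export
emit_registry <- function(cohort, dir, write_dvhs = FALSE, n_bins = 50) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (write_dvhs) {
    dvh_dir <- file.path(dir, "dvh")
    dir.create(dvh_dir, showWarnings = FALSE)
    labels <- c(parotid_ipsi_mean = "parotid_ipsi",
                parotid_contra_mean = "parotid_contra",
                smg_ipsi_mean = "smg_ipsi",
                smg_contra_mean = "smg_contra")
    for (i in seq_len(nrow(cohort))) {
      dvhs <- lapply(names(labels), function(col) {
        generate_dvh(cohort[[col]][i], n_bins = n_bins,
                     structure = labels[[col]], volume_cc = 25)
      })
      names(dvhs) <- labels
      f <- file.path(dvh_dir, paste0(cohort$patient_id[i], ".csv"))
      write_dvh(dvhs, f)
      cohort$dvh_file[i] <- file.path("dvh",
                                      paste0(cohort$patient_id[i], ".csv"))
    }
  }
  path <- file.path(dir, "cohort.csv")
  write_cohort(cohort, path)
  invisible(path)
}
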