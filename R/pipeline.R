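#' Build model features from a cohort table
#'
#' Reduces the per-gland dosimetry of a cohort to the two dose features of
#' the xerostomia model: the summed parotid mean dose and the combined
#' submandibular mean dose, plus the baseline category (with `missing`
#' mapped to `none`, the assumption used when baseline data are sparse).
#'
#' With `dose = "eqd2"`, per-patient DVH files are read, converted to EQD2
#' under the linear-quadratic model (alpha/beta from `alpha_beta`) using
#' each patient's prescription fractionation, and reduced to mean doses.
#' With `dose = "physical"` the stored per-gland mean-dose summaries are
#' used directly and dosimetry is skipped.
#'
#' @param cohort A cohort data frame.
#' @param dose `"physical"` or `"eqd2"`.
#' @param smg_combination `"combined"` (absolute-volume-weighted over both
#'   glands, falling back to equal weights when volumes are unknown),
#'   `"mean"` or `"sum"`.
#' @param alpha_beta Alpha/beta ratio in Gy for EQD2 conversion.
#' @param base_dir Directory against which relative `dvh_file` paths are
#'   resolved.
#' @return Feature data frame with columns `parotid_sum`, `smg`,
#'   `baseline`.
#' @export
featurize_cohort <- function(cohort, dose = c("physical", "eqd2"),
                             smg_combination = c("combined", "mean", "sum"),
                             alpha_beta = 3, base_dir = ".") {
  dose <- match.arg(dose)
  smg_combination <- match.arg(smg_combination)
  baseline <- ifelse(cohort$baseline_xerostomia == "missing", "none",
                     cohort$baseline_xerostomia)
  if (dose == "physical") {
    comb <- if (smg_combination == "sum") "sum" else "mean"
    return(data.frame(
      parotid_sum = cohort$parotid_ipsi_mean + cohort$parotid_contra_mean,
      smg = smg_combined(cohort$smg_ipsi_mean, cohort$smg_contra_mean, comb),
      baseline = baseline))
  }
  if (all(is.na(cohort$dvh_file))) {
    abort_config(paste(
      "dose = 'eqd2' requires per-patient DVH files;",
      "stored mean-dose summaries are physical doses"))
  }
  n <- nrow(cohort)
  parotid_sum <- numeric(n)
  smg <- numeric(n)
  for (i in seq_len(n)) {
    f <- cohort$dvh_file[i]
    if (is.na(f)) {
      abort_data(sprintf("record %s has no DVH file", cohort$patient_id[i]))
    }
    path <- if (file.exists(f)) f else file.path(base_dir, f)
    dvhs <- read_dvh(path)
    scheme <- fractionation(cohort$prescribed_dose_gy[i],
                            cohort$n_fractions[i], alpha_beta)
    eq <- lapply(dvhs, eqd2_transform, scheme = scheme)
    parotid_sum[i] <- mean_dose(eq[["parotid_ipsi"]]) +
      mean_dose(eq[["parotid_contra"]])
    pair <- list(eq[["smg_ipsi"]], eq[["smg_contra"]])
    smg[i] <- switch(smg_combination,
                     combined = {
                       vols <- vapply(pair, function(d) d$volume_cc,
                                      numeric(1))
                       combined_mean_dose(pair, equal_volume = anyNA(vols))
                     },
                     mean = combined_mean_dose(pair, equal_volume = TRUE),
                     sum = mean_dose(pair[[1]]) + mean_dose(pair[[2]]))
  }
  data.frame(parotid_sum = parotid_sum, smg = smg, baseline = baseline)
}

#' Analysis run configuration
#'
#' @param input Either a `cohort_config` (synthetic mode) or the path of a
#'   registry cohort CSV.
#' @param model An `ntcp_model` or the path of a model JSON file; default
#'   the published LIPP model.
#' @param criteria An [inclusion_criteria()] object; its follow-up window
#'   also drives endpoint selection.
#' @param followup_target Target follow-up time in months.
#' @param dose Dose representation, `"physical"` or `"eqd2"`.
#' @param smg_combination Submandibular combination rule (see
#'   [featurize_cohort()]).
#' @param dose_transform Dose transform of the evaluated model
#'   (`NULL` keeps the model's own setting).
#' @param hl_df Hosmer-Lemeshow df convention.
#' @param alpha Closed-test significance level.
#' @param thresholds Decision-curve threshold grid.
#' @param n_bins Calibration-curve risk groups.
#' @param seed Seed for synthetic-mode generation.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = cohort_config(),
                       model = lipp_model(),
                       criteria = inclusion_criteria(),
                       followup_target = 6,
                       dose = c("physical", "eqd2"),
                       smg_combination = c("combined", "mean", "sum"),
                       dose_transform = NULL,
                       hl_df = c("g", "g-2"),
                       alpha = 0.05,
                       thresholds = seq(0.05, 0.60, by = 0.05),
                       n_bins = 10,
                       seed = NULL) {
  dose <- match.arg(dose)
  smg_combination <- match.arg(smg_combination)
  hl_df <- match.arg(hl_df)
  if (is.character(model)) model <- read_ntcp_model(model)
  stopifnot(inherits(model, "ntcp_model"))
  if (!is.null(dose_transform)) {
    model$dose_transform <- match.arg(dose_transform, c("identity", "sqrt"))
  }
  if (!inherits(input, "cohort_config") && !is.character(input)) {
    abort_config("input must be a cohort_config or a cohort CSV path")
  }
  if (!0.30 %in% thresholds) thresholds <- sort(c(thresholds, 0.30))
  structure(list(input = input, model = model, criteria = criteria,
                 followup_target = followup_target, dose = dose,
                 smg_combination = smg_combination, hl_df = hl_df,
                 alpha = alpha, thresholds = thresholds, n_bins = n_bins,
                 seed = seed),
            class = "run_config")
}

report_to_list <- function(report) {
  list(n = report$n, n_events = report$n_events,
       mean_predicted = report$mean_predicted,
       observed_rate = report$observed_rate,
       citl_intercept = report$citl_intercept,
       calibration_intercept = report$calibration_intercept,
       calibration_slope = report$calibration_slope,
       log_likelihood = report$log_likelihood,
       auc = report$auc,
       hl_statistic = report$hl_statistic,
       hl_df = report$hl_df,
       hl_p = report$hl_p,
       brier = report$brier,
       model_provenance = report$model_provenance)
}

#' Run the full external-validation pipeline
#'
#' Generates or loads the registry, applies the inclusion cascade, selects
#' follow-ups and derives endpoints, builds dose features, validates the
#' model, runs the closed testing procedure, validates the chosen update,
#' and computes the decision curve. Writes `report.json`,
#' `calibration_curve.csv`/`.png`, `decision_curve.csv`/`.png`,
#' `exclusion_flow.json`, `cohort_summary.csv` and `run_log.txt` to
#' `out_dir`. Runs are deterministic given the seed: re-running with the
#' same configuration reproduces `report.json` byte for byte.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `report` (original model),
#'   `report_updated`, `decision` (the closed-test `update_decision`),
#'   `decision_curve`, `summary` and `tally`.
#' @export
run_validation <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (missing(out_dir)) abort_config("out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (inherits(config$input, "cohort_config")) {
    gen_cfg <- config$input
    if (!is.null(config$seed)) gen_cfg$seed <- config$seed
    cohort <- generate_cohort(gen_cfg)
    base_dir <- out_dir
  } else {
    cohort <- read_cohort(config$input)
    base_dir <- dirname(config$input)
  }

  incl <- apply_inclusion(cohort, config$criteria)
  included <- incl$included
  window <- config$criteria$followup_window
  ep <- cohort_endpoints(included, config$followup_target, window)
  keep <- !is.na(ep$outcome)
  included <- included[keep, , drop = FALSE]
  y <- ep$outcome[keep]
  if (length(unique(y)) < 2) {
    abort_fit("included cohort has a constant outcome; validation impossible")
  }

  features <- featurize_cohort(included, dose = config$dose,
                               smg_combination = config$smg_combination,
                               base_dir = base_dir)
  model <- config$model

  report <- validate_model(model, features, y, n_bins = config$n_bins,
                           hl_df = config$hl_df)
  decision <- closed_test(model, features, y, alpha = config$alpha)
  report_updated <- validate_model(decision$updated_model, features, y,
                                   n_bins = config$n_bins,
                                   hl_df = config$hl_df)
  p <- stats::predict(model, features)
  dc <- decision_curve(p, y, config$thresholds)
  summ <- cohort_summary(included, config$followup_target, window)
  cm30 <- confusion_at_threshold(p, y, 0.30)
  nb30 <- net_benefit(p, y, 0.30)

  sensitivity_config <- !isTRUE(all.equal(window, c(5, 24)))
  settings <- list(
    mode = if (inherits(config$input, "cohort_config")) "synthetic"
           else "cohort_csv",
    dose = config$dose,
    smg_combination = config$smg_combination,
    dose_transform = model$dose_transform,
    followup_target = config$followup_target,
    followup_window = window,
    hl_df = config$hl_df,
    alpha = config$alpha,
    n_bins = config$n_bins,
    seed = config$seed,
    sensitivity_analysis = sensitivity_config)

  report_json <- list(
    settings = settings,
    exclusion_flow = list(n_input = attr(incl$tally, "n_input"),
                          n_remaining = attr(incl$tally, "n_remaining"),
                          counts = as.list(stats::setNames(
                            incl$tally$n_excluded, incl$tally$criterion))),
    n_analysed = length(y),
    validation = report_to_list(report),
    closed_test = list(chosen_level = decision$chosen_level,
                       alpha = decision$alpha,
                       log_likelihoods = as.list(decision$log_likelihoods),
                       lr_tests = decision$lr_tests),
    updated = report_to_list(report_updated),
    updated_model = list(intercept = decision$updated_model$intercept,
                         coef_parotid = decision$updated_model$coef_parotid,
                         coef_smg = decision$updated_model$coef_smg),
    threshold_030 = list(sensitivity = cm30$sensitivity,
                         specificity = cm30$specificity,
                         net_benefit = nb30))
  jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report_json$exclusion_flow,
                       file.path(out_dir, "exclusion_flow.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$calibration_curve,
                   file.path(out_dir, "calibration_curve.csv"),
                   row.names = FALSE)
  utils::write.csv(dc, file.path(out_dir, "decision_curve.csv"),
                   row.names = FALSE)
  summ_df <- data.frame(
    metric = c("n", "n_events", "prevalence_percent",
               "followup_median_months",
               paste0(names(summ$gland_doses), "_median")),
    value = c(summ$n, summ$n_events, summ$prevalence_percent_1dp,
              summ$followup_median,
              vapply(summ$gland_doses, function(q) unname(q["median"]),
                     numeric(1))))
  utils::write.csv(summ_df, file.path(out_dir, "cohort_summary.csv"),
                   row.names = FALSE)

  try({
    ggplot2::ggsave(file.path(out_dir, "calibration_curve.png"),
                    plot_calibration(report), width = 5, height = 5,
                    dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "decision_curve.png"),
                    plot_decision_curve(dc), width = 6, height = 4,
                    dpi = 150)
  }, silent = TRUE)

  log_lines <- c(
    sprintf("ntcpval run: %s mode", settings$mode),
    sprintf("dose representation: %s; smg combination: %s; dose transform: %s",
            settings$dose, settings$smg_combination,
            settings$dose_transform),
    sprintf("follow-up: target %s months, window [%s, %s]%s",
            settings$followup_target, window[1], window[2],
            if (sensitivity_config) " (sensitivity-analysis configuration)"
            else ""),
    sprintf("HL df convention: %s; alpha: %s; risk bins: %s",
            settings$hl_df, settings$alpha, settings$n_bins),
    sprintf("seed: %s", if (is.null(settings$seed)) "none"
            else settings$seed),
    sprintf("records in: %d; analysed: %d; events: %d",
            report_json$exclusion_flow$n_input, length(y), sum(y)),
    sprintf("closed test chose: %s", decision$chosen_level))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(report = report, report_updated = report_updated,
                 decision = decision, decision_curve = dc, summary = summ,
                 tally = incl$tally))
}

#' Calibration-curve plot
#'
#' Observed event fraction against mean predicted probability per risk
#' bin (abscissa: mean predicted probability within the bin), with the
#' identity line of perfect calibration.
#'
#' @param report A `validation_report`.
#' @return A ggplot object.
#' @export
plot_calibration <- function(report) {
  curve <- report$calibration_curve
  ggplot2::ggplot(curve,
                  ggplot2::aes(x = mean_predicted, y = observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = n), shape = 1) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted probability",
                  y = "Observed frequency",
                  size = "Patients",
                  title = "Calibration by risk decile") +
    ggplot2::theme_minimal()
}

#' Decision-curve plot
#'
#' @param dc Output of [decision_curve()].
#' @return A ggplot object.
#' @export
plot_decision_curve <- function(dc) {
  long <- rbind(
    data.frame(threshold = dc$threshold, net_benefit = dc$net_benefit,
               policy = "model"),
    data.frame(threshold = dc$threshold, net_benefit = dc$nb_treat_all,
               policy = "treat all"),
    data.frame(threshold = dc$threshold, net_benefit = dc$nb_treat_none,
               policy = "treat none"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = threshold, y = net_benefit,
                               colour = policy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.05, max(long$net_benefit) + 0.02)) +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit") +
    ggplot2::theme_minimal()
}

#' Compare two validation reports on the same cohort
#'
#' @param report_original,report_updated `validation_report` objects
#'   computed on the same patients.
#' @return Data frame with one row per metric: original, updated, delta.
#' @export
compare_models <- function(report_original, report_updated) {
  if (report_original$n != report_updated$n) {
    abort_data("reports were computed on different cohort sizes")
  }
  metrics <- c("mean_predicted", "observed_rate", "citl_intercept",
               "calibration_intercept", "calibration_slope",
               "log_likelihood", "auc", "hl_statistic", "hl_p", "brier")
  orig <- vapply(metrics, function(m) report_original[[m]], numeric(1))
  upd <- vapply(metrics, function(m) report_updated[[m]], numeric(1))
  data.frame(metric = metrics, original = unname(orig),
             updated = unname(upd), delta = unname(upd - orig))
}
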