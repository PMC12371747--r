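#' Closed testing procedure for model updating
#'
#' Selects among four nested candidates for an externally validated
#' logistic model: the original model (0 free parameters), an intercept
#' update / calibration-in-the-large (1), recalibration of intercept and
#' slope (2), and full revision of the intercept and both dose
#' coefficients (3). Likelihood-ratio statistics `2 * (LL_a - LL_b)` are
#' referred to chi-square distributions with df equal to the difference in
#' free parameters.
#'
#' The closed-testing cascade tests the largest model against each nested
#' candidate and accepts the simplest candidate that is not rejected:
#' revision vs original (df 3) — if not significant, keep the original;
#' otherwise revision vs intercept update (df 2) — if not significant,
#' update the intercept; otherwise revision vs recalibration (df 1) — if
#' not significant, recalibrate; otherwise revise. This controls the
#' overall type-I error of updating at `alpha`.
#'
#' @param model The original `ntcp_model` under validation.
#' @param features Feature data frame (see [linear_predictor()]).
#' @param y Binary outcomes (both classes required).
#' @param alpha Significance level for every test (default 0.05).
#' @param refit_baseline Passed to [update_model()] for the revision level.
#' @return An object of class `update_decision` with elements
#'   `chosen_level`, `log_likelihoods`, `lr_tests` (data frame:
#'   comparison, statistic, df, p_value), `alpha`, `updated_model` and
#'   `models` (all four fitted candidates).
#' @export
closed_test <- function(model, features, y, alpha = 0.05,
                        refit_baseline = FALSE) {
  stopifnot(inherits(model, "ntcp_model"))
  y <- check_binary(y)
  if (length(unique(y)) < 2) {
    abort_fit("both outcome classes are required for the closed test")
  }
  features <- check_features(features)
  lp <- linear_predictor(model, features)

  models <- list(original = model)
  for (lev in c("intercept", "recalibration", "revision")) {
    models[[lev]] <- tryCatch(
      update_model(model, y, level = lev, features = features, lp = lp,
                   refit_baseline = refit_baseline),
      error = function(e) {
        abort_fit(sprintf("fit failed at update level '%s': %s", lev,
                          conditionMessage(e)))
      })
  }
  ll <- vapply(models, function(m) {
    log_likelihood(stats::predict(m, features), y)
  }, numeric(1))

  # nesting implies monotone log-likelihoods (up to optimizer tolerance)
  if (any(diff(ll) < -1e-6)) {
    abort_fit("log-likelihoods are not monotone over the nested hierarchy")
  }

  n_par <- vapply(names(models), n_free_parameters, integer(1))
  # revision gains extra free parameters when baseline varies in the data
  bs <- baseline_score(model, as.character(features$baseline))
  cats_present <- setdiff(unique(as.character(features$baseline)), "none")
  if (refit_baseline && length(cats_present) > 0) {
    n_par[["revision"]] <- n_par[["revision"]] + length(cats_present)
  } else if (length(unique(bs)) > 1) {
    n_par[["revision"]] <- n_par[["revision"]] + 1L
  }
  comparisons <- c("revision_vs_original", "revision_vs_intercept",
                   "revision_vs_recalibration")
  ref_levels <- c("original", "intercept", "recalibration")
  lr <- data.frame(
    comparison = comparisons,
    statistic = 2 * (ll[["revision"]] - ll[ref_levels]),
    df = n_par[["revision"]] - n_par[ref_levels],
    row.names = NULL)
  lr$statistic <- pmax(lr$statistic, 0)
  lr$p_value <- stats::pchisq(lr$statistic, lr$df, lower.tail = FALSE)

  chosen <- if (lr$p_value[1] >= alpha) {
    "original"
  } else if (lr$p_value[2] >= alpha) {
    "intercept"
  } else if (lr$p_value[3] >= alpha) {
    "recalibration"
  } else {
    "revision"
  }

  structure(
    list(chosen_level = chosen,
         log_likelihoods = ll,
         lr_tests = lr,
         alpha = alpha,
         updated_model = models[[chosen]],
         models = models),
    class = "update_decision")
}

#' @export
print.update_decision <- function(x, ...) {
  cat(sprintf("Closed testing procedure (alpha = %.2f): chosen level '%s'\n",
              x$alpha, x$chosen_level))
  cat("Log-likelihoods:\n")
  for (lev in names(x$log_likelihoods)) {
    cat(sprintf("  %-14s %.2f\n", lev, x$log_likelihoods[[lev]]))
  }
  cat("Likelihood-ratio tests:\n")
  print.data.frame(x$lr_tests, row.names = FALSE, digits = 4)
  invisible(x)
}
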