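#' Binomial log-likelihood
#'
#' @param p Predicted probabilities, strictly inside (0, 1) unless the
#'   corresponding outcome makes the term finite.
#' @param y Binary outcomes.
#' @return Sum of `y*log(p) + (1-y)*log(1-p)`.
#' @export
log_likelihood <- function(p, y) {
  y <- check_binary(y)
  if (length(p) != length(y)) abort_data("p and y lengths differ")
  check_prob(p, open = FALSE)
  if (any((p == 0 & y == 1) | (p == 1 & y == 0))) {
    abort_domain("log-likelihood is -Inf: degenerate prediction contradicts outcome")
  }
  sum(ifelse(y == 1, log(p), log1p(-p)))
}

#' Calibration-in-the-large
#'
#' Mean predicted risk, observed event rate, and the maximum-likelihood
#' intercept `a` of `logit p = a + lp` with the model's linear predictor
#' held as a fixed offset (i.e. the calibration intercept conditional on
#' slope 1).
#'
#' @param p Predicted probabilities in (0, 1).
#' @param y Binary outcomes.
#' @return List with `mean_predicted`, `observed_rate`,
#'   `intercept` (NA with a warning when the outcome is constant).
#' @export
calibration_in_the_large <- function(p, y) {
  y <- check_binary(y)
  check_prob(p)
  if (length(p) != length(y) || length(p) == 0) {
    abort_data("p and y must be nonempty and of equal length")
  }
  out <- list(mean_predicted = mean(p), observed_rate = mean(y),
              intercept = NA_real_)
  if (length(unique(y)) < 2) {
    warning("constant outcome: offset intercept cannot be fitted",
            call. = FALSE)
    return(out)
  }
  lp <- stats::qlogis(p)
  fit <- check_glm_fit(
    stats::glm(y ~ 1, family = stats::binomial(), offset = lp,
               control = glm_ctrl()),
    "calibration-in-the-large")
  out$intercept <- unname(stats::coef(fit)[1])
  out
}

#' Calibration slope and intercept
#'
#' Joint maximum-likelihood fit of `logit p = a + b * lp` on the model's
#' linear predictor; `(a, b) = (0, 1)` indicates perfect weak calibration.
#' The intercept is reported from the joint fit (conditional on the fitted
#' slope); see [calibration_in_the_large()] for the slope-fixed-at-1
#' convention.
#'
#' @param lp Linear predictors (logits) of the model under evaluation.
#' @param y Binary outcomes (both classes must be present).
#' @return Named numeric vector `c(intercept =, slope =)`.
#' @export
calibration_slope_intercept <- function(lp, y) {
  y <- check_binary(y)
  if (!all(is.finite(lp))) abort_data("linear predictors must be finite")
  if (length(unique(y)) < 2) {
    abort_fit("both outcome classes are required to fit the calibration model")
  }
  fit <- check_glm_fit(
    stats::glm(y ~ lp, family = stats::binomial(), control = glm_ctrl()),
    "calibration slope/intercept")
  co <- stats::coef(fit)
  c(intercept = unname(co[1]), slope = unname(co[2]))
}

# Equal-count risk groups by sorted p; the remainder is spread over the
# lowest bins. Groups whose boundary falls inside a run of tied predictions
# are merged (with a warning), since an equal-count split is then undefined.
risk_groups <- function(p, n_bins) {
  n <- length(p)
  if (n < n_bins) abort_data("need at least one observation per bin")
  ord <- order(p)
  sizes <- rep(n %/% n_bins, n_bins)
  rem <- n %% n_bins
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  grp <- rep(seq_len(n_bins), times = sizes)
  g <- integer(n)
  g[ord] <- grp
  # a run of tied predictions must not be split across bins: give every
  # member of such a run the lowest bin label in the run, then relabel
  merged <- FALSE
  for (v in unique(p[duplicated(p)])) {
    at <- p == v
    if (length(unique(g[at])) > 1) {
      g[at] <- min(g[at])
      merged <- TRUE
    }
  }
  if (merged) {
    warning("tied predictions across bin boundaries: bins merged",
            call. = FALSE)
    g <- match(g, sort(unique(g)))
  }
  g
}

#' Calibration curve by equal-count risk bins
#'
#' Groups patients into equal-count bins of sorted predicted probability
#' (deciles by default) and tabulates, per bin, the patient count, the mean
#' predicted probability and the observed event fraction.
#'
#' @param p Predicted probabilities.
#' @param y Binary outcomes.
#' @param n_bins Number of risk groups (default 10).
#' @return Data frame with columns `bin`, `n`, `mean_predicted`,
#'   `observed`, ordered by increasing predicted risk.
#' @export
calibration_curve <- function(p, y, n_bins = 10) {
  y <- check_binary(y)
  check_prob(p, open = FALSE)
  if (length(p) != length(y)) abort_data("p and y lengths differ")
  g <- risk_groups(p, n_bins)
  bins <- sort(unique(g))
  out <- data.frame(
    bin = seq_along(bins),
    n = vapply(bins, function(b) sum(g == b), integer(1)),
    mean_predicted = vapply(bins, function(b) mean(p[g == b]), numeric(1)),
    observed = vapply(bins, function(b) mean(y[g == b]), numeric(1)))
  out
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Chi-square comparison of observed and expected event counts over
#' equal-count risk bins:
#' \deqn{X^2 = \sum_g (O_g - E_g)^2 / (n_g \bar p_g (1 - \bar p_g))}
#' with \eqn{E_g = n_g \bar p_g}. The reference distribution uses `g - 2`
#' degrees of freedom by default (the development-data convention); for a
#' fully external validation, where no parameter was estimated on the
#' evaluation data, `df = "g"` is the appropriate reference.
#'
#' @param p Predicted probabilities.
#' @param y Binary outcomes.
#' @param g Number of risk groups (default 10).
#' @param df Degrees-of-freedom convention, `"g-2"` or `"g"` (counts
#'   effective bins after any tie merging).
#' @return List with `statistic`, `df`, `p_value`, and the underlying
#'   `bins` table.
#' @export
hosmer_lemeshow <- function(p, y, g = 10, df = c("g-2", "g")) {
  df <- match.arg(df)
  curve <- calibration_curve(p, y, n_bins = g)
  pbar <- curve$mean_predicted
  if (any(pbar <= 0 | pbar >= 1)) {
    # a bin with degenerate mean prediction has zero binomial variance;
    # merge it with its neighbour
    warning("bin with degenerate mean prediction merged with neighbour",
            call. = FALSE)
    keep <- pbar > 0 & pbar < 1
    bad <- which(!keep)
    for (b in bad) {
      nb <- if (b == nrow(curve)) b - 1L else b + 1L
      ntot <- curve$n[b] + curve$n[nb]
      curve$mean_predicted[nb] <-
        (curve$n[b] * curve$mean_predicted[b] +
           curve$n[nb] * curve$mean_predicted[nb]) / ntot
      curve$observed[nb] <-
        (curve$n[b] * curve$observed[b] + curve$n[nb] * curve$observed[nb]) /
        ntot
      curve$n[nb] <- ntot
    }
    curve <- curve[keep, , drop = FALSE]
    pbar <- curve$mean_predicted
  }
  o <- curve$n * curve$observed
  e <- curve$n * pbar
  stat <- sum((o - e)^2 / (curve$n * pbar * (1 - pbar)))
  g_eff <- nrow(curve)
  dof <- if (df == "g-2") g_eff - 2L else g_eff
  if (dof < 1) abort_data("too few effective bins for the Hosmer-Lemeshow test")
  list(statistic = stat, df = dof,
       p_value = stats::pchisq(stat, dof, lower.tail = FALSE),
       bins = curve)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and outcome.
#'
#' @param p Predicted probabilities.
#' @param y Binary outcomes.
#' @return Brier score in \[0, 1\].
#' @export
brier <- function(p, y) {
  y <- check_binary(y)
  check_prob(p, open = FALSE)
  if (length(p) != length(y) || length(p) == 0) {
    abort_data("p and y must be nonempty and of equal length")
  }
  mean((p - y)^2)
}

#' Area under the ROC curve
#'
#' Rank-sum (Wilcoxon) estimator with midrank tie handling: the
#' probability that a randomly chosen event case receives a higher
#' prediction than a randomly chosen non-event case, counting ties as 1/2.
#'
#' @param p Predicted probabilities (any monotone score works).
#' @param y Binary outcomes (both classes required).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(p, y) {
  y <- check_binary(y)
  if (length(p) != length(y)) abort_data("p and y lengths differ")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    abort_domain("AUC is undefined with a single outcome class")
  }
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full validation report for an NTCP model on a cohort
#'
#' Computes the complete external-validation metric bundle: observed and
#' predicted risk, calibration-in-the-large intercept (slope fixed at 1),
#' joint calibration slope and intercept, log-likelihood, AUC,
#' Hosmer-Lemeshow test, Brier score and the decile calibration curve.
#'
#' @param model An `ntcp_model`.
#' @param features Feature data frame (see [linear_predictor()]).
#' @param y Binary outcomes.
#' @param n_bins Calibration-curve / HL risk groups.
#' @param hl_df Hosmer-Lemeshow df convention (`"g"` is appropriate for a
#'   fully external validation; `"g-2"` is the development convention).
#' @return An object of class `validation_report`.
#' @export
validate_model <- function(model, features, y, n_bins = 10,
                           hl_df = c("g", "g-2")) {
  hl_df <- match.arg(hl_df)
  y <- check_binary(y)
  lp <- linear_predictor(model, features)
  p <- stats::plogis(lp)
  citl <- calibration_in_the_large(p, y)
  ab <- calibration_slope_intercept(lp, y)
  hl <- hosmer_lemeshow(p, y, g = n_bins, df = hl_df)
  structure(
    list(n = length(y),
         n_events = sum(y),
         mean_predicted = citl$mean_predicted,
         observed_rate = citl$observed_rate,
         citl_intercept = citl$intercept,
         calibration_intercept = unname(ab["intercept"]),
         calibration_slope = unname(ab["slope"]),
         log_likelihood = log_likelihood(p, y),
         auc = auc(p, y),
         hl_statistic = hl$statistic,
         hl_df = hl$df,
         hl_p = hl$p_value,
         brier = brier(p, y),
         calibration_curve = hl$bins,
         dose_transform = model$dose_transform,
         model_provenance = model$provenance),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("External validation report (%s; dose transform: %s)\n",
              x$model_provenance, x$dose_transform))
  cat(sprintf("  n = %d, events = %d (observed %.1f%%, mean predicted %.1f%%)\n",
              x$n, x$n_events, 100 * x$observed_rate,
              100 * x$mean_predicted))
  cat(sprintf("  calibration: in-the-large intercept %.3f; joint intercept %.3f, slope %.3f\n",
              x$citl_intercept, x$calibration_intercept,
              x$calibration_slope))
  cat(sprintf("  log-likelihood %.1f, AUC %.3f, Brier %.3f\n",
              x$log_likelihood, x$auc, x$brier))
  cat(sprintf("  Hosmer-Lemeshow X^2 = %.2f on %d df, p = %.3g\n",
              x$hl_statistic, x$hl_df, x$hl_p))
  invisible(x)
}
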