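#' Logistic NTCP model for grade >= 2 xerostomia
#'
#' Container for a two-dose-term logistic NTCP model of the form
#' \deqn{S = \beta_0 + \beta_p T(D_{par,ipsi} + D_{par,contra}) +
#'           \beta_s T(D_{SMG}) + \mathrm{baseline\ score}}
#' \deqn{NTCP = (1 + e^{-S})^{-1}}
#' where the dose terms are mean doses in Gy, `T` is an optional per-term
#' dose transform, and the baseline score encodes pre-treatment xerostomia
#' severity as a fixed additive offset.
#'
#' @param intercept Model intercept \eqn{\beta_0}.
#' @param coef_parotid Coefficient per Gy on the (transformed) sum of the
#'   ipsilateral and contralateral parotid mean doses.
#' @param coef_smg Coefficient per Gy on the (transformed) submandibular
#'   mean dose.
#' @param baseline_scores Named numeric map for categories `none`, `mild`,
#'   `moderate_severe`; `none` must map to 0.
#' @param dose_transform `"identity"` or `"sqrt"`, applied to each dose
#'   term before multiplying by its coefficient.
#' @param provenance Free-text provenance (original / recalibrated /
#'   revised plus fitting info).
#' @return An object of class `ntcp_model`.
#' @seealso [lipp_model()], [linear_predictor()], [update_model()]
#' @export
ntcp_model <- function(intercept, coef_parotid, coef_smg,
                       baseline_scores = c(none = 0, mild = 0.459,
                                           moderate_severe = 1.207),
                       dose_transform = c("identity", "sqrt"),
                       provenance = "user-defined") {
  dose_transform <- match.arg(dose_transform)
  need <- c("none", "mild", "moderate_severe")
  if (!all(need %in% names(baseline_scores))) {
    abort_config("baseline_scores must name none, mild and moderate_severe")
  }
  if (abs(baseline_scores[["none"]]) > 1e-12) {
    abort_config("baseline_scores['none'] must equal 0")
  }
  structure(
    list(intercept = as.numeric(intercept),
         coef_parotid = as.numeric(coef_parotid),
         coef_smg = as.numeric(coef_smg),
         baseline_scores = baseline_scores[need],
         dose_transform = dose_transform,
         provenance = provenance),
    class = "ntcp_model")
}

#' @export
print.ntcp_model <- function(x, ...) {
  cat("Logistic NTCP model (grade >= 2 xerostomia)\n")
  cat(sprintf("  S = %.4f + %.4f * T(parotid ipsi+contra Dmean) + %.4f * T(SMG Dmean) + baseline\n",
              x$intercept, x$coef_parotid, x$coef_smg))
  cat(sprintf("  dose transform: %s;  baseline scores: none %.3f, mild %.3f, moderate_severe %.3f\n",
              x$dose_transform, x$baseline_scores[["none"]],
              x$baseline_scores[["mild"]], x$baseline_scores[["moderate_severe"]]))
  cat(sprintf("  provenance: %s\n", x$provenance))
  invisible(x)
}

#' The LIPP xerostomia model
#'
#' The published model from the Dutch national indication protocol for
#' proton therapy, predicting grade >= 2 xerostomia at 6 months after
#' radiotherapy from the summed parotid mean dose, the submandibular mean
#' dose and a baseline xerostomia score.
#'
#' @param dose_transform Dose transform to use (`"identity"` is the formula
#'   as published).
#' @return An `ntcp_model`.
#' @export
#' @examples
#' m <- lipp_model()
#' predict(m, data.frame(parotid_sum = 44.5, smg = 55.7, baseline = "none"))
lipp_model <- function(dose_transform = "identity") {
  ntcp_model(-2.2951, 0.0996, 0.0182,
             dose_transform = dose_transform,
             provenance = "LIPP v2.2 published coefficients")
}

#' The LIPP model recalibrated to the KUH registry cohort
#'
#' Published intercept and dose coefficients of the recalibrated model
#' (baseline scores scaled by the same recalibration slope).
#'
#' @return An `ntcp_model`.
#' @export
lipp_recalibrated_model <- function() {
  b <- 0.1354 / 0.0996
  ntcp_model(-3.2132, 0.1354, 0.0247,
             baseline_scores = c(none = 0, mild = 0.459 * b,
                                 moderate_severe = 1.207 * b),
             provenance = "LIPP recalibrated to KUH cohort (published)")
}

#' Baseline xerostomia score
#'
#' @param model An `ntcp_model`.
#' @param category Character vector of baseline categories (`none`, `mild`,
#'   `moderate_severe`).
#' @return Numeric score(s).
#' @export
baseline_score <- function(model, category) {
  stopifnot(inherits(model, "ntcp_model"))
  bad <- setdiff(unique(category), names(model$baseline_scores))
  if (length(bad) > 0) {
    abort_data(sprintf("unknown baseline xerostomia category: %s",
                       paste(bad, collapse = ", ")))
  }
  unname(model$baseline_scores[category])
}

dose_transform_fun <- function(model) {
  switch(model$dose_transform, identity = identity, sqrt = sqrt)
}

check_features <- function(features) {
  need <- c("parotid_sum", "smg", "baseline")
  if (!is.data.frame(features) || !all(need %in% names(features))) {
    abort_data(sprintf("features must be a data frame with columns %s",
                       paste(need, collapse = ", ")))
  }
  if (any(features$parotid_sum < 0) || any(features$smg < 0)) {
    abort_domain("mean doses must be >= 0")
  }
  features
}

#' Linear predictor of an NTCP model
#'
#' @param model An `ntcp_model`.
#' @param features Data frame with columns `parotid_sum` (Gy; ipsilateral +
#'   contralateral parotid mean dose), `smg` (Gy; combined submandibular
#'   mean dose) and `baseline` (category).
#' @return Numeric vector of linear predictors S.
#' @export
linear_predictor <- function(model, features) {
  stopifnot(inherits(model, "ntcp_model"))
  features <- check_features(features)
  tf <- dose_transform_fun(model)
  model$intercept +
    model$coef_parotid * tf(features$parotid_sum) +
    model$coef_smg * tf(features$smg) +
    baseline_score(model, as.character(features$baseline))
}

#' Predicted complication probability
#'
#' @param object An `ntcp_model`.
#' @param features See [linear_predictor()].
#' @param ... Unused.
#' @return Probabilities strictly inside (0, 1).
#' @export
predict.ntcp_model <- function(object, features, ...) {
  stats::plogis(linear_predictor(object, features))
}

n_free_parameters <- function(level) {
  switch(level, original = 0L, intercept = 1L, recalibration = 2L,
         revision = 3L)
}

glm_ctrl <- function() stats::glm.control(epsilon = 1e-10, maxit = 100)

check_glm_fit <- function(fit, what) {
  if (!fit$converged) {
    abort_fit(sprintf("%s fit did not converge", what))
  }
  if (any(abs(stats::coef(fit)) > 1e3)) {
    abort_fit(sprintf(
      "%s fit appears separated (coefficient magnitude > 1e3)", what))
  }
  fit
}

#' Update an NTCP model on external data
#'
#' Fits one of the three nested update levels by maximum likelihood and
#' folds the fitted parameters back into absolute model coefficients:
#'
#' * `intercept` (calibration-in-the-large): `logit p = a + lp` with the
#'   original linear predictor `lp` as a fixed offset; the new intercept is
#'   `beta0 + a`.
#' * `recalibration`: `logit p = a + b * lp`; the new intercept is
#'   `a + b * beta0`, both dose coefficients and the baseline scores are
#'   scaled by `b` (the baseline score is a component of `lp`, so exact
#'   equivalence requires scaling it too; with an all-`none` cohort this is
#'   indistinguishable from leaving it fixed).
#' * `revision`: full refit of the intercept and both dose coefficients.
#'   In a cohort without baseline variation the baseline score enters as a
#'   fixed offset (its effects are not re-estimable there); when baseline
#'   scores do vary, a slope on the baseline score is estimated as well,
#'   so that revision remains a superset of recalibration, and with
#'   `refit_baseline = TRUE` the individual category effects are refitted.
#'
#' @param model The original `ntcp_model`.
#' @param y Binary outcome vector (grade >= 2 xerostomia).
#' @param level `"intercept"`, `"recalibration"` or `"revision"`.
#' @param features Feature data frame (required for `revision`, and used to
#'   compute `lp` when `lp` is not given).
#' @param lp Optional precomputed linear predictors of `model` on the data.
#' @param refit_baseline Re-estimate baseline category effects during
#'   revision (requires baseline variation in the data).
#' @return The updated `ntcp_model`.
#' @export
update_model <- function(model, y, level = c("intercept", "recalibration",
                                             "revision"),
                         features = NULL, lp = NULL,
                         refit_baseline = FALSE) {
  stopifnot(inherits(model, "ntcp_model"))
  level <- match.arg(level)
  y <- check_binary(y)
  if (length(unique(y)) < 2) {
    abort_fit("outcome is constant; update levels cannot be fitted")
  }
  if (is.null(lp)) {
    if (is.null(features)) {
      abort_config("either 'features' or 'lp' must be supplied")
    }
    lp <- linear_predictor(model, features)
  }
  if (length(lp) != length(y)) abort_data("lp and y lengths differ")

  if (level == "intercept") {
    fit <- check_glm_fit(
      stats::glm(y ~ 1, family = stats::binomial(), offset = lp,
                 control = glm_ctrl()),
      "intercept update")
    a <- unname(stats::coef(fit)[1])
    out <- model
    out$intercept <- model$intercept + a
    out$provenance <- sprintf("intercept update (a = %.6g) of [%s]",
                              a, model$provenance)
    return(out)
  }

  if (level == "recalibration") {
    fit <- check_glm_fit(
      stats::glm(y ~ lp, family = stats::binomial(), control = glm_ctrl()),
      "recalibration")
    a <- unname(stats::coef(fit)[1])
    b <- unname(stats::coef(fit)[2])
    out <- model
    out$intercept <- a + b * model$intercept
    out$coef_parotid <- b * model$coef_parotid
    out$coef_smg <- b * model$coef_smg
    out$baseline_scores <- model$baseline_scores * b
    out$provenance <- sprintf(
      "recalibration (a = %.6g, b = %.6g) of [%s]", a, b, model$provenance)
    return(out)
  }

  # revision
  if (is.null(features)) {
    abort_config("'features' are required for model revision")
  }
  features <- check_features(features)
  tf <- dose_transform_fun(model)
  x1 <- tf(features$parotid_sum)
  x2 <- tf(features$smg)
  bs <- baseline_score(model, as.character(features$baseline))
  if (refit_baseline && length(unique(features$baseline)) > 1) {
    bl <- factor(as.character(features$baseline),
                 levels = names(model$baseline_scores))
    fit <- check_glm_fit(
      stats::glm(y ~ x1 + x2 + bl, family = stats::binomial(),
                 control = glm_ctrl()),
      "revision")
    co <- stats::coef(fit)
    scores <- model$baseline_scores
    for (cat in c("mild", "moderate_severe")) {
      nm <- paste0("bl", cat)
      if (nm %in% names(co) && !is.na(co[nm])) scores[[cat]] <- unname(co[nm])
    }
    out <- ntcp_model(unname(co["(Intercept)"]), unname(co["x1"]),
                      unname(co["x2"]), baseline_scores = scores,
                      dose_transform = model$dose_transform,
                      provenance = sprintf(
                        "revision (refit incl. baseline) of [%s]",
                        model$provenance))
    return(out)
  }
  if (length(unique(bs)) > 1) {
    # with baseline variation, estimate a slope on the baseline score so
    # that revision nests recalibration (which scales the scores by b)
    fit <- check_glm_fit(
      stats::glm(y ~ x1 + x2 + bs, family = stats::binomial(),
                 control = glm_ctrl()),
      "revision")
    co <- stats::coef(fit)
    return(ntcp_model(
      unname(co["(Intercept)"]), unname(co["x1"]), unname(co["x2"]),
      baseline_scores = model$baseline_scores * unname(co["bs"]),
      dose_transform = model$dose_transform,
      provenance = sprintf("revision (incl. baseline slope) of [%s]",
                           model$provenance)))
  }
  fit <- check_glm_fit(
    stats::glm(y ~ x1 + x2, family = stats::binomial(), offset = bs,
               control = glm_ctrl()),
    "revision")
  co <- stats::coef(fit)
  ntcp_model(unname(co["(Intercept)"]), unname(co["x1"]), unname(co["x2"]),
             baseline_scores = model$baseline_scores,
             dose_transform = model$dose_transform,
             provenance = sprintf("revision of [%s]", model$provenance))
}

#' Serialize / deserialize NTCP models
#'
#' Models are stored as flat JSON mirroring the fields of [ntcp_model()].
#'
#' @param model An `ntcp_model`.
#' @param path File path.
#' @return `read_ntcp_model` returns an `ntcp_model`; `write_ntcp_model`
#'   returns `path` invisibly.
#' @export
write_ntcp_model <- function(model, path) {
  stopifnot(inherits(model, "ntcp_model"))
  jsonlite::write_json(
    list(intercept = model$intercept,
         coef_parotid = model$coef_parotid,
         coef_smg = model$coef_smg,
         baseline_scores = as.list(model$baseline_scores),
         dose_transform = model$dose_transform,
         provenance = model$provenance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ntcp_model
#' @export
read_ntcp_model <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("model file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ntcp_model(x$intercept, x$coef_parotid, x$coef_smg,
             baseline_scores = unlist(x$baseline_scores),
             dose_transform = x$dose_transform,
             provenance = x$provenance)
}
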