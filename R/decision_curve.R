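#' Confusion counts at a probability threshold
#'
#' Classifies `p >= t` as predicted positive and tabulates the confusion
#' matrix with derived sensitivity and specificity.
#'
#' @param p Predicted probabilities.
#' @param y Binary outcomes.
#' @param t Threshold strictly inside (0, 1).
#' @return List with `threshold`, `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`.
#' @export
confusion_at_threshold <- function(p, y, t) {
  y <- check_binary(y)
  if (length(p) != length(y)) abort_data("p and y lengths differ")
  if (t <= 0 || t >= 1) abort_domain("threshold must lie strictly in (0, 1)")
  pos <- p >= t
  tp <- sum(pos & y == 1)
  fp <- sum(pos & y == 0)
  tn <- sum(!pos & y == 0)
  fn <- sum(!pos & y == 1)
  list(threshold = t, tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Net benefit at a probability threshold
#'
#' Standard decision-curve net benefit:
#' `NB = TP/n - (FP/n) * t/(1-t)`; the treat-all policy has
#' `NB = prevalence - (1 - prevalence) * t/(1-t)` and treat-none has 0.
#'
#' @inheritParams confusion_at_threshold
#' @return Net benefit of the `p >= t` classification rule.
#' @export
net_benefit <- function(p, y, t) {
  cm <- confusion_at_threshold(p, y, t)
  n <- length(y)
  cm$tp / n - (cm$fp / n) * t / (1 - t)
}

#' Decision curve over a threshold grid
#'
#' @param p Predicted probabilities.
#' @param y Binary outcomes.
#' @param thresholds Threshold grid strictly inside (0, 1); the default
#'   grid is 0.05 to 0.60 in steps of 0.05, which includes the clinically
#'   anchored 0.30 threshold.
#' @return Data frame with one row per threshold: confusion counts,
#'   sensitivity, specificity, `net_benefit`, `nb_treat_all`,
#'   `nb_treat_none`.
#' @export
decision_curve <- function(p, y, thresholds = seq(0.05, 0.60, by = 0.05)) {
  y <- check_binary(y)
  thresholds <- sort(thresholds)
  prev <- mean(y)
  rows <- lapply(thresholds, function(t) {
    cm <- confusion_at_threshold(p, y, t)
    data.frame(threshold = t, tp = cm$tp, fp = cm$fp, tn = cm$tn,
               fn = cm$fn, sensitivity = cm$sensitivity,
               specificity = cm$specificity,
               net_benefit = cm$tp / length(y) -
                 (cm$fp / length(y)) * t / (1 - t),
               nb_treat_all = prev - (1 - prev) * t / (1 - t),
               nb_treat_none = 0)
  })
  do.call(rbind, rows)
}
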