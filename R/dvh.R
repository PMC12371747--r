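#' Dose-volume histogram objects
#'
#' A `dvh` stores the cumulative dose-volume curve for one organ-at-risk
#' structure: the fraction of the structure volume receiving at least each
#' dose level. This is the dosimetric input unit for mean-dose NTCP models
#' of the salivary glands.
#'
#' @param structure Structure label; one of the controlled vocabulary
#'   `"parotid_ipsi"`, `"parotid_contra"`, `"smg_ipsi"`, `"smg_contra"`, or
#'   `"other"`.
#' @param dose_gy Numeric vector of bin edge doses in Gy, strictly
#'   increasing, starting at 0.
#' @param cum_volume Fraction of structure volume receiving at least each
#'   dose in `dose_gy`: non-increasing, first entry 1, last entry 0, all in
#'   \[0, 1\].
#' @param volume_cc Absolute structure volume in cm^3 (optional; required
#'   for volume-weighted combination of paired structures).
#'
#' @return An object of class `dvh`.
#' @seealso [mean_dose()], [eqd2_transform()], [cumulative_to_differential()]
#' @export
#' @examples
#' d <- dvh("parotid_ipsi", c(0, 10, 20), c(1, 0.4, 0), volume_cc = 28)
#' mean_dose(d)
dvh <- function(structure, dose_gy, cum_volume, volume_cc = NA_real_) {
  structure <- match.arg(structure, dvh_structures())
  if (length(dose_gy) != length(cum_volume) || length(dose_gy) < 2) {
    abort_data(sprintf(
      "DVH for '%s': dose and volume vectors must have equal length >= 2",
      structure))
  }
  if (any(dose_gy < 0) || any(diff(dose_gy) <= 0)) {
    abort_data(sprintf(
      "DVH for '%s': bin doses must be non-negative and strictly increasing",
      structure))
  }
  if (abs(dose_gy[1]) > 1e-9) {
    abort_data(sprintf("DVH for '%s': first bin edge must be 0 Gy", structure))
  }
  if (any(cum_volume < -1e-9) || any(cum_volume > 1 + 1e-9)) {
    abort_data(sprintf(
      "DVH for '%s': cumulative volumes must lie in [0, 1]", structure))
  }
  if (any(diff(cum_volume) > 1e-9)) {
    abort_data(sprintf(
      "invalid DVH for structure '%s': cumulative volume is not non-increasing",
      structure))
  }
  if (abs(cum_volume[1] - 1) > 1e-9) {
    abort_data(sprintf(
      "DVH for '%s': cumulative volume at 0 Gy must equal 1", structure))
  }
  if (abs(cum_volume[length(cum_volume)]) > 1e-9) {
    abort_data(sprintf(
      "DVH for '%s': cumulative volume must reach 0 at the final bin",
      structure))
  }
  structure(
    list(structure = structure,
         dose_gy = as.numeric(dose_gy),
         cum_volume = pmin(pmax(as.numeric(cum_volume), 0), 1),
         volume_cc = as.numeric(volume_cc)),
    class = "dvh")
}

dvh_structures <- function() {
  c("parotid_ipsi", "parotid_contra", "smg_ipsi", "smg_contra", "other")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("DVH for %s: %d bins, 0-%.1f Gy, mean dose %.2f Gy%s\n",
              x$structure, length(x$dose_gy) - 1, max(x$dose_gy),
              mean_dose(x),
              if (is.na(x$volume_cc)) "" else
                sprintf(", volume %.1f cc", x$volume_cc)))
  invisible(x)
}

#' Fractionation scheme
#'
#' Prescription-level fractionation used for EQD2 conversion under the
#' linear-quadratic model. The per-bin fraction dose is taken as the bin
#' dose divided by the number of fractions of the course (uniform
#' fractionation assumed per bin, which matches simultaneous-integrated
#' boost delivery where every voxel is treated in every fraction).
#'
#' @param prescribed_dose Prescription dose in Gy (> 0).
#' @param n_fractions Number of fractions (>= 1).
#' @param alpha_beta Alpha/beta ratio in Gy; 3 Gy is the conventional value
#'   for late salivary-gland toxicity.
#' @return An object of class `fractionation`.
#' @export
fractionation <- function(prescribed_dose, n_fractions, alpha_beta = 3) {
  if (!is.numeric(prescribed_dose) || prescribed_dose <= 0) {
    abort_config("prescribed_dose must be > 0")
  }
  if (n_fractions < 1 || n_fractions != round(n_fractions)) {
    abort_config("n_fractions must be a positive integer")
  }
  if (alpha_beta <= 0) abort_config("alpha_beta must be > 0")
  structure(list(prescribed_dose = prescribed_dose,
                 n_fractions = as.integer(n_fractions),
                 alpha_beta = alpha_beta),
            class = "fractionation")
}

#' Convert a cumulative DVH to differential form
#'
#' @param x A [dvh()] object.
#' @return A data frame with columns `dose_mid` (bin midpoint, Gy) and
#'   `volume_fraction` (fraction of structure volume in the bin); the
#'   fractions sum to 1.
#' @export
#' @examples
#' cumulative_to_differential(dvh("other", c(0, 10, 20), c(1, 0.4, 0)))
cumulative_to_differential <- function(x) {
  stopifnot(inherits(x, "dvh"))
  frac <- -diff(x$cum_volume)
  mid <- (x$dose_gy[-1] + x$dose_gy[-length(x$dose_gy)]) / 2
  data.frame(dose_mid = mid, volume_fraction = frac)
}

#' EQD2 of a single dose level
#'
#' Equivalent dose in 2-Gy fractions under the linear-quadratic model:
#' `EQD2 = D * (d + alpha/beta) / (2 + alpha/beta)` where `d` is the dose
#' per fraction, here `D / n_fractions`. At exactly 2 Gy per fraction the
#' conversion is the identity.
#'
#' @param dose Physical dose in Gy (vectorised, >= 0).
#' @param scheme A [fractionation()] object.
#' @return EQD2 in Gy.
#' @export
#' @examples
#' eqd2_bin(60, fractionation(60, 30))        # 2 Gy/fx fixed point: 60
#' eqd2_bin(51.68, fractionation(51.68, 34))  # 46.72
eqd2_bin <- function(dose, scheme) {
  stopifnot(inherits(scheme, "fractionation"))
  if (any(dose < 0)) abort_domain("dose must be >= 0 for EQD2 conversion")
  d <- dose / scheme$n_fractions
  dose * (d + scheme$alpha_beta) / (2 + scheme$alpha_beta)
}

#' EQD2-transform a DVH
#'
#' Applies [eqd2_bin()] to every bin edge of a cumulative DVH, leaving the
#' volume axis unchanged. The LQ map is strictly increasing for dose >= 0,
#' so the output satisfies the DVH invariants whenever the input does.
#'
#' @param x A [dvh()] object.
#' @param scheme A [fractionation()] object.
#' @return A [dvh()] with EQD2 bin edges.
#' @export
eqd2_transform <- function(x, scheme) {
  stopifnot(inherits(x, "dvh"))
  dvh(x$structure, eqd2_bin(x$dose_gy, scheme), x$cum_volume, x$volume_cc)
}

#' Mean dose of a DVH
#'
#' Volume-weighted mean of the differential bin midpoints.
#'
#' @param x A [dvh()] object.
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(x) {
  stopifnot(inherits(x, "dvh"))
  d <- cumulative_to_differential(x)
  sum(d$dose_mid * d$volume_fraction)
}

#' Combined mean dose over several structures
#'
#' Absolute-volume-weighted mean dose over a set of structures (e.g. both
#' submandibular glands treated as one organ). With a single structure this
#' reduces to [mean_dose()].
#'
#' @param dvhs List of [dvh()] objects.
#' @param equal_volume If `TRUE`, weight structures equally instead of by
#'   `volume_cc` (fallback when absolute volumes are unknown).
#' @return Combined mean dose in Gy.
#' @export
combined_mean_dose <- function(dvhs, equal_volume = FALSE) {
  stopifnot(length(dvhs) >= 1, all(vapply(dvhs, inherits, TRUE, "dvh")))
  means <- vapply(dvhs, mean_dose, numeric(1))
  if (equal_volume) return(mean(means))
  vols <- vapply(dvhs, function(d) d$volume_cc, numeric(1))
  if (anyNA(vols)) {
    abort_config(paste(
      "absolute structure volumes are required for combined mean dose;",
      "set equal_volume = TRUE to weight structures equally"))
  }
  sum(means * vols) / sum(vols)
}

#' Read per-patient DVH files
#'
#' Reads a CSV with columns `structure,dose_gy,cum_volume_fraction` and
#' optionally `volume_cc`, one block of rows per structure, and returns a
#' named list of [dvh()] objects keyed by structure label.
#'
#' @param path Path to the DVH CSV file.
#' @return Named list of `dvh` objects.
#' @export
read_dvh <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("DVH file not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("structure", "dose_gy", "cum_volume_fraction")
  if (!all(need %in% names(tab))) {
    abort_data(sprintf("DVH file %s must have columns %s", path,
                       paste(need, collapse = ", ")))
  }
  out <- lapply(split(tab, tab$structure), function(block) {
    vol <- if ("volume_cc" %in% names(block)) block$volume_cc[1] else NA_real_
    ord <- order(block$dose_gy)
    dvh(block$structure[1], block$dose_gy[ord],
        block$cum_volume_fraction[ord], vol)
  })
  out[unique(tab$structure)]
}

#' Write DVHs to a per-patient CSV
#'
#' Inverse of [read_dvh()].
#'
#' @param dvhs Named list of [dvh()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dvh <- function(dvhs, path) {
  rows <- lapply(dvhs, function(d) {
    data.frame(structure = d$structure, dose_gy = d$dose_gy,
               cum_volume_fraction = d$cum_volume,
               volume_cc = d$volume_cc)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
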