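# Fixture builders shared across the suite. Everything is generated in
# code; no data files are read.

# Minimal valid cohort data frame with per-patient overrides.
make_cohort <- function(n,
                        year = 2018,
                        site = "oropharynx",
                        dose = 68,
                        n_fx = 34L,
                        baseline = "missing",
                        parotid_ipsi = 28, parotid_contra = 16,
                        smg_ipsi = 65, smg_contra = 46,
                        fu_times = list(6),
                        fu_grades = list(0L),
                        adaptation = FALSE, brachy = FALSE,
                        reirradiation = FALSE,
                        contoured = TRUE) {
  rep_n <- function(x) rep_len(x, n)
  rep_list <- function(x) rep_len(if (is.list(x)) x else list(x), n)
  data.frame(
    patient_id = sprintf("T%04d", seq_len(n)),
    treatment_year = rep_n(year),
    tumor_site = rep_n(site),
    prescribed_dose_gy = rep_n(dose),
    n_fractions = rep_n(n_fx),
    baseline_xerostomia = rep_n(baseline),
    parotid_ipsi_mean = rep_n(parotid_ipsi),
    parotid_contra_mean = rep_n(parotid_contra),
    smg_ipsi_mean = rep_n(smg_ipsi),
    smg_contra_mean = rep_n(smg_contra),
    dvh_file = rep_n(NA_character_),
    flag_adaptation = rep_n(adaptation),
    flag_brachy = rep_n(brachy),
    flag_reirradiation = rep_n(reirradiation),
    glands_contoured = rep_n(contoured),
    stringsAsFactors = FALSE
  ) |> within({
    followup_times <- rep_list(fu_times)
    followup_grades <- rep_list(fu_grades)
  })
}

# Random valid cumulative DVH with the given number of bins.
random_dvh <- function(n_bins = 50, max_dose = 70, structure = "other",
                       volume_cc = NA_real_) {
  edges <- c(0, sort(runif(n_bins - 1, 0, max_dose)), max_dose)
  w <- runif(n_bins)
  w <- w / sum(w)
  cum <- c(1, 1 - cumsum(w))
  cum[length(cum)] <- 0
  dvh(structure, edges, cum, volume_cc)
}

# Simple feature set with a wide, informative linear predictor.
random_features <- function(n) {
  data.frame(parotid_sum = runif(n, 10, 80),
             smg = runif(n, 20, 75),
             baseline = sample(c("none", "mild", "moderate_severe"), n,
                               replace = TRUE, prob = c(0.8, 0.15, 0.05)))
}
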