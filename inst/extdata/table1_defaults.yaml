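'n': 674
rho: 0.4
dose_targets:
  gland:
  - parotid_ipsi
  - parotid_contra
  - smg_ipsi
  - smg_contra
  median:
  - 28.3
  - 16.2
  - 65.2
  - 46.2
  q25:
  - 22.4
  - 11.0
  - 59.0
  - 39.6
  q75:
  - 37.9
  - 19.6
  - 67.6
  - 51.7
baseline_probs:
  none: 0.83
  mild: 0.16
  moderate_severe: 0.01
baseline_recorded: 0.15
delta_a: 0.0
delta_b: 1.0
followup_window:
- 5.0
- 24.0
followup_median: 10.3
exclusion_counts:
  plan_adaptation: 61
  brachy_boost: 34
  reirradiation: 71
prevalence_target: 0.3
dose_cap: 90.0
smg_combination: mean
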