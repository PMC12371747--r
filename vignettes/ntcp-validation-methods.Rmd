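---
title: "Methods: external validation and updating of a xerostomia NTCP model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: external validation and updating of a xerostomia NTCP model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntcpval)
```

## The model

`ntcpval` is organised around a two-dose-term logistic NTCP model for
grade ≥ 2 xerostomia,

$$S = \beta_0 + \beta_p\,T(D_{par}) + \beta_s\,T(D_{smg}) + b(x),
\qquad \mathrm{NTCP} = (1+e^{-S})^{-1},$$

where $D_{par}$ is the sum of the ipsilateral and contralateral parotid
mean doses (Gy), $D_{smg}$ the combined submandibular mean dose, $b(x)$ a
fixed additive score for the pre-treatment xerostomia category (0 for
none, 0.459 for mild, 1.207 for moderate–severe), and $T$ an optional
per-term dose transform. `lipp_model()` carries the published LIPP
coefficients $(\beta_0, \beta_p, \beta_s) = (-2.2951, 0.0996, 0.0182)$.

The model assumes a linear dose effect on the logit scale, additivity of
the two gland terms, and a baseline effect that is fixed rather than
estimated. Patients with no recorded baseline are scored as `none`, the
assumption used when validating on registries where baseline assessment is
sparse; the raw category is retained in the cohort table so baseline-aware
analyses remain possible.

### The dose-transform ambiguity

Published two-gland xerostomia models exist in both identity-dose and
square-root-dose variants, and the printed formula is not always
numerically consistent with the other quantities printed alongside it:
with the identity transform, typical registry dose levels (parotid sum
≈ 45 Gy, submandibular ≈ 56 Gy) give $S \approx 3.2$, i.e. predicted risks
above 0.9, which is far from the reported mean predicted risks of such
cohorts (≈ 0.3–0.4). Both transforms are therefore implemented
(`dose_transform = "identity"` or `"sqrt"`), the identity form — the
formula as printed — is the default, and the transform in force is stated
in every validation report. The pipeline never switches transforms
silently; the ambiguity cannot be resolved from the published material
alone.

## Dosimetric preprocessing

DVHs are cumulative curves (fraction of structure volume receiving at
least each dose). Differential bins use the midpoint of adjacent edges as
the representative dose — unbiased for piecewise-uniform curves — and the
mean dose is the volume-weighted mean of those midpoints.

EQD2 conversion uses the linear-quadratic model with
$\alpha/\beta = 3$ Gy (late salivary-gland toxicity):
$\mathrm{EQD2} = D\,(d + \alpha/\beta)/(2 + \alpha/\beta)$ with the
per-fraction dose $d = D/n_{fx}$ taken from the prescription's fraction
number. This per-bin rule assumes every voxel is treated in every fraction,
which matches simultaneous-integrated-boost delivery. The conversion is
the identity at exactly 2 Gy per fraction and strictly increasing in dose,
so transformed DVHs remain valid.

When the registry stores per-gland mean doses rather than DVHs, dosimetry
is skipped and the summaries are used directly (`featurize_cohort(dose =
"physical")`); EQD2 of a mean dose is not the mean of the EQD2 DVH, so the
package refuses to approximate it and requires DVHs for EQD2 analyses.

How the two submandibular glands enter the single $D_{smg}$ term is
configurable (`smg_combination`): `"combined"` weights the per-gland means
by absolute structure volume (falling back to equal weights when volumes
are unknown), `"mean"` averages them, `"sum"` adds them. The volume-
weighted combination is the default because it equals the mean dose of the
union structure; the published formula writes one term for two glands and
does not fix the rule.

## Cohort assembly

The inclusion cascade (treatment years, eligible tumor sites, glands
contoured, prescribed dose ≥ 50 Gy as the curative-intent proxy, at least
one follow-up in the window, then plan adaptation, brachytherapy boost and
reirradiation) is applied sequentially, attributing every excluded patient
to the *first* criterion failed. This mirrors how exclusion flow charts
count overlapping criteria and makes the tally conserve patients exactly:
input = remaining + sum of per-criterion counts. Patients with no
in-window follow-up are tallied under a dedicated `no_followup_in_window`
criterion rather than silently dropped.

The endpoint assessment is the follow-up nearest 6 months (the assessment
time of the development cohort) within a configurable window, 5–24 months
by default; ties are broken toward the earlier visit, which is closer to
the 6-month standard in expectation because late follow-ups dominate the
window. Setting the window to 5–12 months reproduces the narrower
sensitivity-analysis configuration, and `run_validation()` flags such runs
in the report.

## Update levels and coefficient folding

`update_model()` fits three nested updates of a validated model by maximum
likelihood, with the original linear predictor $\ell$ computed on the
evaluation data:

* **intercept** (calibration-in-the-large): $\mathrm{logit}\,p = a + \ell$
  with $\ell$ as a fixed offset; folded as $\beta_0 \mapsto \beta_0 + a$.
* **recalibration**: $\mathrm{logit}\,p = a + b\,\ell$; folded as
  $\beta_0 \mapsto a + b\beta_0$, both dose coefficients scaled by $b$,
  and — because the baseline score is a component of $\ell$ — the baseline
  scores scaled by $b$ as well. In an all-`none` cohort this last step is
  unobservable, but it is required for the folded model to be *exactly*
  the fitted recalibration on cohorts with baseline variation.
* **revision**: refit of the intercept and both dose coefficients. In a
  cohort without baseline variation the baseline score enters as a fixed
  offset (its effect is not identifiable there, and revision has 3 free
  parameters). When baseline scores vary, a slope on the baseline score is
  estimated too (4 free parameters): without it, revision would not nest
  recalibration — recalibration scales the baseline scores, which a
  fixed-offset revision cannot represent — and the likelihood-ratio
  ordering of the closed test could be violated. A `refit_baseline` flag
  instead refits free per-category effects.

All logistic fits use `stats::glm` with a tightened convergence control
(relative change $10^{-10}$, 100 iterations); fits that fail to converge
or produce coefficient magnitudes above $10^3$ (the separation guard) are
reported as classed fitting errors, never as numbers.

## The closed testing procedure

`closed_test()` compares the nested hierarchy original (0 free
parameters) → intercept (1) → recalibration (2) → revision (3, or more
with baseline variation as above) through likelihood-ratio statistics
$2\Delta LL$ with df equal to the difference in free parameters. Following
the closed-testing principle, the largest model is tested against each
nested candidate and the simplest non-rejected candidate is accepted:
revision vs original — if not significant keep the original; else revision
vs intercept; else revision vs recalibration; else revise. Every test is
performed at the global level $\alpha = 0.05$, which bounds the overall
probability of updating a correct model at $\alpha$. The log-likelihood
ordering over the hierarchy is asserted on every run.

## Validation metrics and their conventions

* **Calibration intercept**: two conventions exist, and reports carry
  both. The *joint* intercept comes from the two-parameter fit
  $\mathrm{logit}\,p = a + b\ell$ (the weak-calibration framework); the
  *calibration-in-the-large* intercept fixes $b = 1$ (offset fit). They
  answer different questions and differ whenever $b \ne 1$.
* **Calibration curve**: equal-count bins of sorted predicted risk
  (deciles by default), remainder spread over the lowest bins (674
  patients in 10 bins gives four bins of 68 and six of 67). A run of tied
  predictions is never split across bins; affected bins are merged with a
  warning. The curve's abscissa is the mean predicted probability within
  the bin, and this is stated in the plot.
* **Hosmer–Lemeshow**: $X^2 = \sum_g (O_g - E_g)^2 / [n_g \bar p_g
  (1-\bar p_g)]$ over the same bins. The df convention is configurable:
  $g-2$ is the convention for development data, where two parameters were
  estimated; for a *fully external* validation no parameter was estimated
  on the evaluation data and the appropriate reference is $\chi^2_g$. The
  pipeline's external-validation report therefore uses `df = "g"`; with
  `df = "g-2"` the test is anti-conservative in this setting (its
  simulated type-I error roughly doubles).
* **AUC**: the rank-sum estimator with midrank ties — the probability that
  an event case outranks a non-event case, ties counting one half. No
  bootstrap interval is attached by default.
* **Brier score**: mean squared error of the predicted probability; the
  constant-prevalence predictor scores exactly
  $\mathrm{prev}(1-\mathrm{prev})$, a useful reference point.

## Decision curves

Net benefit at threshold $t$ uses the standard form
$NB = TP/n - (FP/n)\,t/(1-t)$, with treat-all
$= \mathrm{prev} - (1-\mathrm{prev})\,t/(1-t)$ and treat-none $= 0$.
Classification is $p \ge t$ (closed at the threshold). The default grid is
0.05–0.60 in steps of 0.05 and always contains 0.30, the threshold
corresponding to common clinical dose constraints (mean parotid dose
< 25 Gy, mean submandibular dose < 39 Gy); thresholds at or above 1 are
rejected because the false-positive weight is unbounded there.

## The synthetic registry generator

The generator exists so that every pipeline stage can be exercised,
end to end and under known truth, without patient data. Its defaults are
the conditions of the registry it emulates:

* **Dose marginals**: per-gland truncated log-normal distributions fitted
  to the published median/IQR targets (ipsilateral parotid 28.3
  [22.4–37.9] Gy, contralateral parotid 16.2 [11.0–19.6], ipsilateral
  submandibular 65.2 [59.0–67.6], contralateral 46.2 [39.6–51.7]).
  Log-normal is a natural two-parameter family for positive, right-skewed
  dose summaries; only three quantiles are published, so the family choice
  is a modelling decision, and the two parameters are fitted by least
  squares on the three quantiles (`calibrate_lognormal()`). Samples are
  truncated at 90 Gy as a plausibility bound.
* **Joint structure**: a Gaussian copula with a single exchangeable
  correlation $\rho = 0.4$ links the four glands. No joint information is
  published; $\rho$ is a sensitivity knob, not an estimate, and moderate
  positive correlation reflects the shared geometry of bilateral neck
  irradiation.
* **True outcome model**: the default (`synthetic_true_model()`) keeps the
  LIPP dose coefficients — hence the published dose-response shape — and
  solves the intercept so that the expected prevalence under the dose
  marginals equals 0.30, the registry's observed rate. This choice is
  forced by the dose-transform inconsistency described above: the printed
  identity-transform coefficients at the printed dose levels predict ≈ 0.9
  prevalence, so no generator can match both the printed coefficients and
  the printed prevalence; the package privileges the dose-response shape
  and the prevalence, which are the quantities the validation statistics
  are sensitive to. The calibration solves a one-dimensional root-finding
  problem on a fixed internal Monte-Carlo sample (2 × 10⁵ draws, fixed
  internal seed), so it is deterministic and does not perturb the
  caller's RNG stream.
* **Miscalibration knobs**: outcomes are drawn from
  $\mathrm{plogis}(\delta_a + \delta_b\,\ell_{true})$; $(\delta_a,
  \delta_b) = (0, 1)$ is neutral. $\delta_b = 1.36$ reproduces the
  situation in which the validated cohort's dose response is steeper than
  the model's and the closed test should recalibrate.
* **Follow-up**: the outcome-carrying assessment time follows a scaled
  Beta on the follow-up window, calibrated to a median of 10.3 months
  (only the median and range of follow-up are published; the Beta shape is
  a documented choice). Additional assessments are placed strictly farther
  from the 6-month target, so the nearest-to-6 selection provably returns
  the primary assessment and its grades encode the drawn outcome; other
  visits receive grades on the same side of the endpoint threshold.
* **Baseline**: recorded for 15% of patients; among those, none / mild /
  moderate-severe at 0.83 / 0.16 / 0.01.
* **Exclusion flow**: disjoint flag sets of 61 / 34 / 71 extra records
  beyond the 674 included, reproducing the published flow of 840 → 674.

What the generator does **not** emulate: spatial dose structure,
site-specific dose correlations, recovery of salivary function over time
(grades are time-constant per patient), inter-observer grading noise, and
informative missingness of follow-up. Passing tests therefore demonstrate
the correctness of the statistical machinery under the registry's marginal
structure, not the clinical performance of any model on real patients.

## Numerical choices and problem sizes

Logistic fits: IRLS via `glm` at relative tolerance $10^{-10}$, 100
iterations, separation guard at $|\hat\beta| > 10^3$. Root finding
(prevalence intercept, Beta shape): `uniroot` at $10^{-10}$. Quantile
fitting: Nelder–Mead at relative tolerance $10^{-14}$. Synthetic DVHs
match their target mean exactly by construction (moment matching followed
by linear rescaling of the dose axis), verified to $10^{-6}$ Gy.

The test suite's simulation sizes are chosen to give decisive checks at
interactive runtimes: closed-test operating characteristics use 500
replicate cohorts of n = 674 per scenario (type-I error of keeping the
original model, and power under $\delta_b = 1.36$); Hosmer–Lemeshow size
uses 1,000 replicates at n = 674; large-sample parameter recovery uses a
single cohort of n = 10⁵, at which the recalibration slope is expected
within 1.00 ± 0.05.

## Known limitations

The package validates a *given* model; it does not develop one. Shrinkage
or penalized updating, smoothed calibration curves, time-to-event
xerostomia modelling, confidence intervals for net benefit, and oral
cavity or stem-cell-region dose terms are out of scope. The chi-square
cohort comparison uses the uncorrected Pearson statistic, so very sparse
tables rely on the category-merging rule rather than exact tests.
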