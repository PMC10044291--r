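---
title: "Evaluating clinical decision rules that rule out radiographic pneumonia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating clinical decision rules that rule out radiographic pneumonia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pneumorule)
```

## The problem and the model

In primary care, a chest X-ray (CXR) is the reference test for pneumonia in
patients with a suspected lower respiratory tract infection, but most CXRs
ordered on clinical grounds show no infiltrate. A clinical decision rule
(CDR) combines bedside signs into a single binary verdict; if the rule's
negative likelihood ratio (LR⁻) is small, a negative rule pushes the
post-test probability of pneumonia low enough that imaging (and empiric
antibiotics) can be withheld.

The statistical objects are simple and everything downstream is arithmetic
on a 2×2 table. Each patient contributes a vector of binary signs derived
from raw measurements at fixed cut-offs and a reference outcome (pneumonia
visible on CXR by radiologist consensus). A rule is a Boolean ANY/ALL
combination of signs; cross-tabulating its verdict against the outcome
gives TP/FP/FN/TN, from which the package computes sensitivity,
specificity, accuracy, predictive values, LR⁺ = Se/(1−Sp),
LR⁻ = (1−Se)/Sp, and — because a binary rule's ROC curve has a single
interior vertex — AUROC = (Se+Sp)/2. Post-test probability follows Bayes in
odds form: `odds_post = odds_pre × LR`.

Two framings of "usefulness" are reported side by side: the *prevented
X-rays* (rule-negative patients, in whom imaging would have been skipped)
and the *missed pneumonia* (false negatives, the safety cost of skipping).

## Dichotomization choices

Cut-offs live in one table (`default_cutoffs()`), with the boundary
handling fixed by the conventional inequality for each sign: fever is
temperature ≥ 37.8 °C (inclusive), hypoxemia SpO₂ < 95 % (strict),
tachycardia heart rate > 100/min (strict), tachypnea respiratory rate
≥ 24/min (inclusive), hypotension SBP ≤ 90 or DBP ≤ 60 mmHg, old age
≥ 65 years. Missing raw values propagate to missing signs and never raise;
analyses use a complete-case policy over the signs they need (no
imputation), mirroring how such cohorts exclude the minority of patients
with unmeasured vitals.

The CRB-65 ≥ 1 flag is derived from the standard severity-score definition
(confusion, respiratory rate ≥ 30/min, low blood pressure, age ≥ 65). It is
excluded from regressions and rules by default: "confusion" is rarely
collected in these cohorts, so the flag is mostly a reporting row, and its
derivation is the package's own choice rather than something the data
dictate.

## Statistical methods and why these variants

* **Group comparisons** use the Yates-corrected χ² on 2×2 tables, switching
  to Fisher's exact test when any expected cell is below 5 — the
  conventional trigger for "where appropriate". The continuity-corrected
  variant is deliberate: on tables of this size (~100 patients) it is the
  default of the mainstream analysis environments and reproduces the
  p-values such analyses report, where the uncorrected statistic can
  differ by a factor of 2–3.
* **Confidence intervals for proportions** are Clopper–Pearson exact (beta
  quantiles). At n = 26 the Wald interval is visibly off (it can cross 0
  or 1); the exact interval is the standard conservative choice for
  diagnostic panels.
* **Likelihood-ratio intervals** use the Simel log-method:
  `exp(log LR ± z·SE)` with `SE(log LR⁻) = √(1/FN − 1/(TP+FN) + 1/TN −
  1/(TN+FP))`.
* **The binary-rule AUROC interval** uses the DeLong variance, which for a
  binary test reduces to `Se(1−Se)/(4(n₊−1)) + Sp(1−Sp)/(4(n₋−1))`. The
  n−1 denominators (the unbiased two-sample U-statistic form) matter at
  these sample sizes and are the reason the interval endpoints agree with
  published panels to the printed precision.
* **Univariate odds ratios** equal the cross-product ratio `ad/bc` with
  Wald intervals on the log scale; a single zero cell triggers the Haldane
  0.5 correction and is flagged, two zero cells in a margin are refused.
  For a binary predictor this is exactly the univariate logistic OR (the
  tests assert the equivalence to 6 decimals).
* **Multivariate modeling** is maximum-likelihood logistic regression with
  backward selection minimizing the AIC. The selection loop refits every
  single-term deletion, records the full AIC trace, and stops when no
  deletion improves the criterion; ties within 1e−12 drop the term
  earliest in the canonical (input column) order, making selection
  deterministic. Degenerate fits — constant outcome, constant predictor,
  non-convergence, or fitted probabilities within 1e−8 of 0/1
  (separation) — raise errors carrying diagnostics rather than returning
  unstable coefficients. Blood pressure is excluded from the default
  candidate set: in rule-out cohorts hypotension can be absent among
  diseased patients, which makes its coefficient infinite.
* **Paired comparisons** of two rules on the same patients: the
  sensitivity difference is estimated from the marginal sensitivities
  (pairing never moves the point estimate) with a Wald interval computed
  after adding 1 to each of the four paired cells (the Laplace adjustment
  of the Bonett–Price family, which repairs the interval's small-sample
  coverage). The LR⁻ ratio is estimated on the log scale by the delta
  method with the multinomial covariance of the paired cells; within each
  disease block the two rules' negative proportions co-vary through the
  both-negative cell. Because published reports rarely include the joint
  (paired) classification, these intervals cannot be checked against
  printed values; they are validated instead by a parametric-bootstrap
  coverage oracle (10 000 multinomial resamples of a fixed truth with all
  expected cells ≥ 5; observed coverage 95.0 % against the nominal 95 %).
  A raw-scale (additive) Wald variant is provided as an option because
  some reports print additive intervals for ratios (intervals that can
  cross zero); the log scale is the default since a ratio's sampling
  distribution is right-skewed.
* **Agreement** between two readers of the same images: Cohen's κ with the
  Fleiss–Cohen–Everitt large-sample standard error, plus specific positive
  agreement `2a/(2a+b+c)`, specific negative agreement `2d/(2d+b+c)`, and
  overall concordance with an exact interval. Specific agreement is
  reported because κ alone hides the asymmetry that readers agree far more
  on absence than on presence of an infiltrate.

Undefined quantities (zero denominators: PPV of a never-positive rule, LR⁻
when specificity is 0, κ when both raters are constant) are returned as
tagged markers with a reason and render as "—" in reports; they never
surface as `NaN` or exceptions mid-pipeline.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions the analysis assumes: a
cohort of 107 patients, prevalence 26/107 (~24 %) of CXR-visible pneumonia,
and per-sign conditional positivity probabilities equal to the observed
group proportions (e.g. fever in 12/26 diseased vs 11/81 non-diseased;
hypoxemia 12/26 vs 17/81; abnormal auscultation 20/26 vs 55/81). Disease
status is Bernoulli; given status, signs are conditionally independent by
default — the minimal (naive-Bayes) structure consistent with published
marginals, since the true sign–sign dependence is unreported. A single
knob `rho` couples the signs through a one-factor Gaussian copula for
sensitivity analyses of that assumption. Raw vitals are back-filled
uniformly within the bin implied by each binary sign (a hypoxemic patient
gets SpO₂ in [85, 94.9], a febrile one a temperature in [37.8, 39.8], and
so on); the bins are a documented convenience — only the binarized values
feed the analysis. One integer seed makes a cohort byte-reproducible, and
generation restores the caller's RNG state.

What passing tests on these cohorts do show: the whole pipeline —
dichotomization, complete-case filtering, rule evaluation, panel
arithmetic, selection, comparisons — is correct under a known generating
process, including parameter recovery of logistic coefficients planted by
`logistic_recovery_fixture()`. What they cannot show: robustness to the
features real cohorts add — correlated signs, measurement rounding
(tympanic thermometers, oximeter quantization), informative missingness,
selection bias in who gets an X-ray, and practice-level clustering. None
of those are modeled.

## Numerical and design notes

* Problem sizes in the test-suite simulations were chosen to keep the
  whole suite comfortably under a half minute while leaving Monte-Carlo
  noise well below the tolerances asserted: 107–1000 patients for
  pipeline checks, 5 000 for recovery fixtures (log-OR standard error
  ≈ 0.1), 50 replicates for selection-frequency checks, 10 000 resamples
  for the bootstrap coverage oracle, 200 000 patients for the
  conditional-independence check (|r| < 0.01).
* AIC backward selection keeps a noise term with probability
  P(χ²₁ > 2) ≈ 0.16, so with three null candidates the *exact* true-term
  set is selected in only ~60 % of replicates even at n = 5 000 — the
  tests assert retention of the true terms (≈100 %) and modal selection of
  the exact set, which is what AIC's behavior actually supports.
* Selection never empties the model: with a single remaining term the
  loop stops (an intercept-only "rule" has no clinical reading here).
* The report bundle (`run_full_analysis()`) computes everything before
  writing anything, contains no timestamps (identical inputs give
  byte-identical bundles), and flags cohorts with an empty outcome group
  as degenerate rather than failing.
* Text renderings print percentages to 0 decimals and ratios to 2, the
  display convention of clinical diagnostic tables; TSV outputs keep full
  precision.
* The R functions are the interface: `run_full_analysis()` plus the
  per-table report builders cover what a command-line wrapper would do,
  and `scripts/acceptance.R` shows the end-to-end invocation.

## Known limitations

* All inference is unclustered; cohorts recruited across many practices
  violate this mildly.
* The binary-rule AUROC and its interval apply only to a single binary
  test; there is no continuous-marker ROC machinery here by design.
* The paired LR⁻-ratio interval relies on asymptotic normality of the log
  ratio; with single-digit false-negative counts it is wide and its
  coverage claim is supported only at expected cell counts ≥ 5.
* The synthetic generator's conditional-independence default understates
  the redundancy of correlated vital signs; effect-size recovery under
  `rho > 0` should be interpreted as a sensitivity analysis, not a
  calibration.
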