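---
title: "Misclassification-corrected prevalence estimation from quota-matched panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Misclassification-corrected prevalence estimation from quota-matched panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(prevadjust)
```

## The estimation problem

Estimating the population prevalence of schizophrenia from a self-completed
web survey faces two compounding obstacles. First, no survey classifier is
perfect: a screening model applied to a general-population sample will call
some healthy respondents positive, and — more severely — will confuse other
psychiatric conditions with the target disorder. Second, the classifier
misses a known fraction of true cases. The crude positive fraction is
therefore a biased estimate of prevalence, typically biased far upward when
the disorder is rare and the confuser classes are common.

`prevadjust` implements a plug-in correction for this situation. It assumes
the analyst knows, from validation studies of the classifier:

* the rate $r_{hc}$ at which healthy individuals are falsely called positive,
* the rates $r_{MDD}$ and $r_{BD}$ at which major depressive disorder and
  bipolar disorder patients are misclassified as the target disorder,
* the population fractions $P_{hc}$, $P_{MDD}$, $P_{BD}$ of those classes, and
* the ratio $p$ of true positives to false negatives among known cases
  (equivalently the sensitivity $p/(1+p)$).

With a sample of size $n$ and $N_{crude}$ classifier positives, the
correction is

$$
N_{fp} = (P_{hc} r_{hc} + P_{MDD} r_{MDD} + P_{BD} r_{BD})\, n, \qquad
N_{tp} = N_{crude} - N_{fp}, \qquad
N_{fn} = N_{tp} / p,
$$

and the adjusted prevalence is

$$
\hat\pi = \frac{N_{crude} - N_{fp} + N_{fn}}{n}.
$$

This is a multi-confuser relative of the Rogan–Gladen estimator: expected
false positives are removed class by class, and the missed cases are
restored through the externally observed true-positive to false-negative
ratio. Conditions outside the healthy/MDD/BD set (the `other` latent class,
e.g. OCD) contribute nothing to $N_{fp}$, by construction of the formula.

## The worked example

Every input to the correction is a published plug-in value, carried by the
default `misclassification_profile()`: $P_{hc} = 0.80$, $r_{hc} = 0.031$,
$P_{MDD} = 0.079$, $r_{MDD} = 0.554$, $P_{BD} = 0.004$, $r_{BD} = 0.594$,
$p = 46{:}15$, $n = 750$. With 62 classifier positives:

```{r}
cx <- correct_prevalence(62, 750)
cx
confusion_table(cx)
tidy(cx)
```

The crude 8.3% collapses to 1.6% once the 53 expected false positives are
removed and the 3 expected false negatives restored. A bootstrap interval on
the 12 adjusted cases:

```{r}
bootstrap_prevalence_ci(12, 750, replicates = 10000, seed = 1)
```

## Study design and the synthetic cohort

The sampling design the package emulates is a quota-matched web panel:
respondents are recruited per demographic cell (five age groups spanning
20–75, two genders, 13 Japanese regions; 130 cells) until each cell's target
count is met, so the sample mirrors a target population composition. The
sample size of 750 follows from the single-proportion formula
$n = Z^2 p(1-p)/e^2$ at $Z = 1.96$, $p = 0.02$, $e = 0.01$
(`required_sample_size(1.96, 0.02, 0.01)` gives 753; the reference design
rounded to 750).

Because the original panel data are proprietary, the package ships a
synthetic cohort generator that reproduces the *structure* of such data:

* `default_composition()` is an explicitly synthetic 130-cell composition
  whose margins resemble Japan's (region weights roughly proportional to
  regional population, decade age bins closed at 20–75, a near-even gender
  split). The real October-2021 census composition is not public in usable
  form here; any user-supplied table is accepted via `read_composition()`.
  Age-group boundaries are likewise a documented assumption (20–29, 30–39,
  40–49, 50–59, 60–75).
* `build_quota_table()` converts proportions to integer quotas by
  largest-remainder apportionment, so each quota is within one respondent of
  exact proportionality and quotas sum exactly to $n$; remainder ties break
  by canonical cell order for determinism.
* `simulate_panel()` draws latent diagnostic classes
  (healthy/MDD/BD/SZ/other) i.i.d. from a `population_mix()` whose defaults
  are the plug-in population fractions, with the schizophrenia share as the
  quantity under study and `other` closing the simplex.
* `generate_features()` draws survey features from class-conditional
  distributions declared in a `feature_schema()`. The default schema spans
  the five survey categories (demographics, health background, physical,
  psychiatric and social comorbidities) with plausibility-chosen effect
  directions (shorter sleep, higher perceived stress, lower ikigai, more
  unemployment among cases). Separations are calibrated so that a classifier
  on these features reaches an ROC AUC in the mid-0.8s for schizophrenia
  versus healthy at development-set scale — comparable to the reference
  classifier's internal validity — with MDD and BD profiles intermediate,
  making them genuine confusers. `null_feature_schema()` removes all
  separation for negative controls.

What the generator deliberately does **not** model: survey participation and
attrition, incentive effects, item nonresponse (the emulated survey rejects
blank answers), within-cell covariance between features beyond what the
class label induces, and any claim about real Japanese prevalence. Passing
tests on synthetic cohorts therefore demonstrate that the estimator and its
software are correct under the stated generating assumptions, not that the
plug-in rates are externally valid.

## The classifier and its oracle stand-in

Two classifier routes feed the correction:

* **Trained mode.** A multilayer perceptron with the reference
  architecture: five rectified-linear hidden layers of 128, 64, 32, 16 and 8
  units, He-normal initialisation, a single sigmoid output. Training
  hyperparameters are not published for the reference model, so the package
  uses conventional defaults for an ~11% positive class — class-weighted
  binary cross-entropy, Adam (step size $10^{-3}$), mini-batches of 32,
  early stopping on a stratified 20% validation split with patience 10 — all
  configurable through `mlp_control()`. Categorical features are one-hot
  encoded and numeric ones z-standardised, with encoding parameters learned
  on the training split only. The decision threshold defaults to 0.5 with
  "$\ge$" at the boundary (the sigmoid midpoint; no published threshold
  exists).
* **Oracle mode.** `oracle_classify()` labels each respondent positive with
  a probability depending only on the latent class, using the published
  validation rates (`oracle_rates()`). This reproduces the error structure
  of the validated classifier without any fitting, which is what the
  correction actually consumes, and isolates correction behaviour from
  optimisation noise. The default schizophrenia sensitivity is $46/61
  \approx 0.754$ rather than the rounded 0.75, keeping the oracle exactly
  consistent with the correction's $46{:}15$ ratio. The `other` class has no
  published misclassification rate and defaults to 0.

Evaluation uses the tie-corrected Mann–Whitney AUC (`auc_mann_whitney()`),
threshold metrics from confusion counts (`classifier_metrics()`), and
stratified 10-fold cross-validation (`cross_validate()`).

Note the internal-validation sensitivity (0.56) differs from the external
one (0.75) for the reference classifier; the correction follows the external
$46{:}15$ ratio, as the correction formula itself does.

## Uncertainty

`bootstrap_prevalence_ci()` resamples the $n$ case indicators with
replacement (equivalently, draws replicate counts from
$\mathrm{Binomial}(n, \hat\pi)$, which is how it is computed) and forms
either a normal-approximation interval ($\hat\pi \pm 1.96\,\mathrm{SD}$ of
replicate prevalences) or a percentile interval. The default is the normal
interval on the adjusted case indicators with 10,000 replicates, which at 12
cases of 750 gives 0.7%–2.5% at one-decimal precision. The percentile
variant is provided and agrees within half a percentage point for counts
above ~30.

`bootstrap_corrected_ci()` additionally propagates the correction itself:
each replicate resamples respondents, recomputes the crude count from their
predicted labels and re-applies the full correction. Plug-in rates are
treated as fixed constants throughout — no uncertainty in $r_{MDD}$ etc. is
propagated, matching the plug-in character of the estimator.

## Numerical and degenerate-input choices

* **Rounding.** False-positive components are kept unrounded and only the
  summed total is rounded, half away from zero (53.2065 → 53); $N_{fn}$
  rounds the same way (2.935 → 3). No single rounding rule can reproduce the
  per-class counts 18/33/2 sometimes quoted alongside the total (the
  components evaluate to 18.60/32.82/1.78), so the per-class values are
  reported unrounded in `fp_components`. Percentages print to one decimal,
  halves away from zero (`format_prevalence()`).
* **Clamping and the raw estimator.** When $N_{fp} > N_{crude}$ — likely in
  bootstrap replicates and at very low true prevalence — $N_{tp}$ clamps to
  zero with a warning, and the headline adjusted count/prevalence clamp to
  $[0, n]$/$[0, 1]$. The unclamped values are retained as
  `n_adjusted_raw`/`adjusted_prevalence_raw` because truncation at zero
  makes the clamped estimator upward-biased when truncation is probable
  (at a true prevalence of 0.5% under the default profile, about a third of
  surveys truncate, for a bias near +0.3 percentage points). Simulation
  assessments of unbiasedness therefore average the raw estimator, the
  standard convention for Rogan–Gladen-type corrections; reported point
  estimates use the clamped value.
* **Determinism.** Every stochastic operation takes a seed and restores the
  caller's RNG state; `run_study()` derives all stage seeds from one master
  seed, so a report regenerates byte-identically. Survey CSVs print doubles
  with 17 significant digits and are re-parsed by `strtod`, so file
  round-trips are bit-exact.
* **Degenerate inputs.** Zero quotas yield empty samples; a panel short of a
  quota cell errors naming the cell; single-class labels error in training
  and evaluation; `case_count = 0` gives a degenerate (0, 0) percentile
  interval.

## Problem sizes used in the test-suite experiments

The packaged experiments run at sizes chosen to make Monte-Carlo noise small
relative to the assertions while keeping the suite quick: class-frequency
checks at panels of 100,000 (20 seeds), oracle rate convergence at 10,000
per class, parameter recovery over 200 simulated surveys of 750 at true
prevalences 0.5%, 1.6% and 5%, interval coverage over 1,000 simulated
surveys with 2,000-replicate bootstraps, and headline intervals at the full
10,000 replicates.

## Known limitations

* The plug-in rates are constants; no joint or Bayesian estimation of rates
  and prevalence, and no propagation of their sampling uncertainty.
* The correction recognises exactly three confuser classes; `other` is
  generated but intentionally ignored, mirroring the target formula.
* Whether the corrected quantity is point or lifetime prevalence depends
  entirely on what the classifier's response variable captured; the package
  is agnostic.
* The crude-prevalence bootstrap here is the indicator bootstrap; externally
  published crude intervals computed under unknown bootstrap designs need
  not match it exactly.
* The MLP is a faithful architectural reimplementation, not the reference
  model's weights; trained-mode results quantify the pipeline, not the
  original classifier.
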