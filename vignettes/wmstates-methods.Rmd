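---
title: "Population spike-train analysis of working-memory on/off states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population spike-train analysis of working-memory on/off states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmstates)
```

## The scientific problem

During spatial working-memory tasks such as the oculomotor delayed response
(ODR) task, neurons in prefrontal (PFC) and posterior parietal (PPC) cortex
fire persistently through a multi-second delay after a cue disappears.
Whether this persistent activity is continuous at the population level, or
interrupted by coordinated "silent" or low-information periods, is a central
question for the mechanism of working-memory maintenance. `wmstates`
implements a family of population-level statistics for trial-structured
multi-unit spike recordings that address this question from several angles:

* **Information time courses** — the bias-corrected percentage of explained
  variance (omega squared) of firing rate by cue location, per unit and time
  bin.
* **Coordinated-silence detection from spike timing** — the population
  inter-spike-interval (ISI) statistic: the maximum ISI of the pooled spike
  train of co-tuned neuron groups, compared against a trial-shuffle null
  through a log-log regression on firing rate.
* **On/off states from decoder confidence** — binary diametric decoding of
  the remembered location with leave-one-out lasso-logistic models, z-scored
  against label-shuffle nulls and segmented into cluster-corrected on states
  and sub-threshold off states; state-conditioned tuning curves, cross-areal
  transfer, spectra, reaction-time and outcome analyses.
* **Simultaneous vs. pseudo-population decoding** — the cost of within-trial
  co-fluctuations for decodable information, measured against populations
  spliced across trials.

All analyses run on a `spike_dataset`: three tidy tables (spike events,
trials, units) with a fixed epoch layout — fixation `[-1, 0)`, cue
`[0, 0.5)`, delay `[0.5, 3.5)`, response `[3.5, 4.1)` seconds relative to
cue onset, eight cue locations at 45-degree spacing (denser stimulus sets
are grouped to the nearest canonical angle). All intervals in the package
are half-open `[start, end)`.

## The synthetic-data generator

No public recordings accompany the analyses this package implements, so the
generator in `simulate_tuned_session()` / `simulate_poisson_population()` is
a first-class, tested component that emulates the statistical structure the
analyses assume — not a biophysical model of persistent activity.

* **Baseline rates** are drawn per neuron from a discrete uniform 1–20 Hz.
* **Tuning** is a von Mises bump: during cue and delay a neuron
  superimposes a tuned Poisson process at rate
  `(gain - 1) * baseline * exp(kappa * (cos(theta - pref) - 1))`, so `gain`
  is the peak-to-baseline ratio at the preferred angle (default 3,
  concentration `kappa = 2`). Ground truth is stored with the dataset for
  recovery tests. Because baseline and tuned spikes are generated as
  superimposed Poisson processes, each spike carries its source, which is
  what lets `impose_off_states()` gate *tuning* while baseline firing
  persists.
* **Surrogate populations** for the ISI validation reproduce the published
  simulation design exactly: 50 populations, 2–20 neurons, 10–20 three-second
  trials, and a paired variant in which 1–3 coordinated silent windows of
  100 ms per trial (placed uniformly; overlaps allowed, deletion acts on the
  union) are removed from all neurons simultaneously. A per-neuron
  independent-silence mode exists for contrast.
* **Off-state gating** alternates on/off states as an exponential
  alternating renewal process: `rate_hz` full on+off cycles per second
  (default 1) and a stationary off-time fraction `off_fraction` (default
  0.5; transient-dip regimes use smaller values, e.g. 0.25 for a mean off
  duration of 0.6 s at `rate_hz = 0.4`). During off states the tuned
  component is thinned by a multiplier in `[0, 1]` while baseline firing
  persists. States are shared across all neurons of an area and optionally
  across areas — the coordination downstream detectors look for.
* **Behavior**: reaction time is `base + beta_state * 1[on at go cue] +
  Gaussian noise`; error probability grows linearly with the off-time
  fraction in the last 0.5 s of the delay.

What the generator deliberately does **not** emulate: noise correlations
beyond state-driven gating, oscillatory structure, rate drift or adaptation
within trials, and realistic saccade dynamics. Passing tests on this
generator therefore demonstrate correctness of the statistics under their
own assumptions, not robustness to every property of cortical data.

## Key parameters and conventions

| Parameter | Default | Meaning |
|---|---|---|
| bin width / step | 0.1 s / 0.05 s | decoder and PEV rate estimation grid |
| PSTH bin | 0.05 s | population-rate and elevation tests |
| `lambda` | 0.01 | lasso penalty of the logistic decoders |
| on-state threshold | z > 1.64 | per-bin confidence z-score |
| cluster criterion | 95th pct of null max cluster mass | family-wise correction over time |
| off-state rule | z < 0.3 for ≥ 3 bins | consecutive 50 ms steps |
| label shuffles | 50 | decoder-confidence null |
| tuning shuffles | 1000 | debiasing of aligned tuning curves |
| ISI shuffles | 10000 | trial-permutation null |
| pseudo-populations | 100 | simultaneous-vs-spliced contrast |
| population gate | ≥ 5 co-tuned selective units | ISI group selection (2–10 sweep supported) |
| cross-areal gate | > 80 source neurons | transfer analyses |
| selectivity | ANOVA p < 0.05 and best rate ≥ 2 Hz | per-unit inclusion |
| laminar classes | 0–0.8 / 0.8–1.2 / ≥ 1.2 mm | superficial / middle / deep |

Conventions that the underlying literature leaves open, fixed here once:

* **Half-open intervals everywhere**; a depth of exactly 1.2 mm is *deep*.
* **ANOVA selectivity** uses epoch-mean rates (spikes/duration) per trial.
* Units with an undefined preferred location (zero resultant) are excluded
  from preferred-location-conditioned analyses, with a logged count.
* **Trial stratification for omega squared** is drawn once per analysis run
  (single seed), so the same balanced trials enter every time bin.
* Negative omega-squared values are retained; clipping would bias the
  one-sample delay test toward positivity.
* **Z-scoring for decoding** uses the full rate matrix across trials (the
  procedure as usually described); a fold-safe variant (`zscore = "fold"`)
  refits means and s.d.s inside each training fold.
* The two-class softmax consumes the margins `(s, -s)` of the single binary
  lasso-logistic fit; any monotone per-class score would do, the softmax
  normalization is what is fixed.
* **Zero-variance features are zeroed, not dropped**, keeping feature
  indices stable across folds.
* **Cluster-mass null**: per label shuffle the *maximum* cluster mass over
  the delay is recorded; the 95th percentile of these maxima is the on-state
  criterion (the max-statistic form of cluster correction, controlling
  family-wise error). The null is per trial, from that trial's 50 shuffled
  traces. Confidence is always that of the trial's true cue class, also on
  error trials.
* **ISI pooling** concatenates spikes within each delay period only —
  no interval spans a trial boundary. The pooled rate denominator is the
  summed delay duration (`n_trials * 3 s`). The trial shuffle permutes each
  neuron's trial identity independently, the minimal operation that breaks
  cross-neuron temporal coordination while preserving every single-neuron
  train; the null regression is iteration-matched (one regression per
  shuffle index across populations).
* The primary one-sided ISI test asks whether the empirical slope is
  *flatter* than the null (the coordinated-silence signature); both tails
  are always reported, since recorded data can and do come out steeper.
* **State counting** uses any-overlap membership in the final 0.5 s window.
* A bin whose null s.d. is zero (possible with few shuffles) falls back to
  the pooled shuffle s.d., with a warning.
* **RT/state sign convention**: `beta_state = RT_on - RT_off`; both
  one-sided bootstrap tails are reported.

## Numerical choices

* `glmnet` fits use `standardize = FALSE` (features are already z-scored),
  a fixed single `lambda = 0.01`, and convergence threshold `1e-6`; the
  optimizer is deterministic, so repeated runs match exactly.
* The beta-mixture EM clamps confidences to `[1e-6, 1 - 1e-6]` (saturated
  classifiers produce exact 0/1), uses weighted beta MLE M-steps via BFGS on
  log-shape parameters, and takes the best of ≥ 10 restarts: a quantile-split
  moment start, a degenerate start at the single-beta fit (which guarantees
  the nested log-likelihood ordering), and random perturbations. AIC/BIC use
  k = 2 and k = 5 parameters from the same log-likelihood implementation, so
  `dBIC - dAIC = 3 (ln n - 2)` exactly.
* The Welch estimator uses 2 s Hamming windows, 50% overlap and a
  1024-point zero-padded FFT; one-sided scaling doubles all bins except DC
  and Nyquist. Mean-center series before calling it.
* Permutation p-values use the add-one convention `(1 + #extreme)/(B + 1)`,
  which is exactly uniform on its lattice under the null.
* `sample()`-style draws go through a guarded integer-range helper so
  degenerate ranges (e.g. a rate range collapsed to one value) behave
  correctly.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script exercise every stage end-to-end on
sizes chosen so the full run completes comfortably on a single CPU while
keeping every statistical conclusion stable under its stated tolerance:
the ISI validation cohort runs all 50 populations with 1000 shuffle
iterations (p resolution 1/1001); calibration uses 200 repetitions of an
8-population cohort at 99 shuffles; the state-detection session uses 12
units and 18 trials per diametric location on the full 100 ms/50 ms delay
grid with the full 50-shuffle null (gating: multiplier 0, 0.2 cycles/s,
off fraction 0.5), and its false-positive control an untuned 12-unit
session; the cross-areal check simulates three replicate sessions per gating
condition, each with 84 source and 84 target units (the > 80 gate) and 12
trials per location, labeling the first 1.5 s of the delay with 20-shuffle
nulls, and tests the depth reduction at the session level; the pseudo-population contrast uses all 100 pseudo-populations of
a 32-unit, 20-trials-per-location diametric session (binary decoder,
gating off fraction 0.25) at five delay bins. Default parameters in
exported functions are the full-scale values quoted above.

## Known limitations

* **Off-state detection sensitivity is bounded.** When an off state carries
  *no* cue information at all, the decoder's confidence during that period
  is statistically exchangeable with its label-shuffle null, so its z-score
  is approximately standard normal and at most `pnorm(0.3) ≈ 62%` of true
  off time can fall below the fixed `z < 0.3` threshold; the 3-consecutive-
  bin rule reduces time-coverage further, to roughly 40–45% in our
  synthetic recovery runs (Jaccard overlap with ground truth ≈ 0.4). The
  rule is, however, highly *precise* (≈ 90% of detected off time is truly
  off), which is what the downstream tuning-depth, transfer, spectral and
  behavioral analyses rely on. Treat labeled off states as a conservative
  subsample of the true low-information periods, not an exhaustive
  segmentation.
* With 100 pseudo-populations the per-bin comparison is an exact
  permutation rank test (two-sided minimum p ≈ 0.02), so Bonferroni flags
  are attainable only over a handful of bins; the empirical percentile of
  the simultaneous accuracy is reported alongside and carries the main
  signal.
* **The simultaneous-vs-pseudo contrast needs both trials and
  redundancy.** Splicing trials dilutes every pseudo-trial's informative
  neuron subset, which corrupts leave-one-out *training* when a class has
  only a few positive examples: at ≤ 10 trials per location the 8-way
  contrast can invert (simultaneous above the pseudo spread) even under
  strong shared gating. The binary diametric decoder reaches adequate
  trial counts at desk scale and exhibits the expected deficit; with
  session-scale trial counts the 8-way scheme behaves equivalently.
* The beta-mixture comparison uses information criteria only; no
  likelihood-ratio calibration across mixture orders is attempted, and
  components beyond two are out of scope.
* **Cross-areal unit-level t-tests pseudoreplicate trial-level state
  noise.** Within one session, every target unit experiences the same
  realization of the target area's own on/off states inside the
  source-selected windows, so the per-unit depth differences share a
  trial-level noise component and the across-unit t-test overstates
  evidence in either direction. `cross_areal_transfer()` reports that
  conventional statistic, but conclusions about the presence or absence of
  coordination should aggregate over sessions (as the shipped checks do).
* Decoding supports the single fixed lasso penalty; alternative classifiers
  and hyperparameter search are out of scope.

## A minimal end-to-end example

```{r example, eval = FALSE}
library(wmstates)

# a tuned synthetic session with coordinated off states
cfg <- sim_config(n_neurons = 12, n_trials_per_location = 18,
                  gain = 5, kappa = 3, seed = 1)
ds  <- simulate_tuned_session(cfg, locations = c(0, 180))
g   <- impose_off_states(ds, multiplier = 0, rate_hz = 0.2, seed = 2)

# decoder-confidence null and state labels
cn <- confidence_null(g$ds, n_shuffles = 50, seed = 3)
lb <- label_states(cn)
autoplot(lb, trial = 1)

# state-conditioned, shuffle-debiased tuning
st <- state_tuning(g$ds, lb, n_shuffles = 1000, seed = 4)
st
autoplot(st)

# the population-ISI silence statistic on surrogate cohorts
h <- isi_validation_harness(seed = 1, n_populations = 50, n_iter = 1000)
h$decisions
```
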