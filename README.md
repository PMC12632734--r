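# wmstates

Population spike-train analysis of working-memory maintenance: information
time courses, coordinated-silence statistics, decoder-confidence on/off
states, and simultaneous vs. pseudo-population decoding — for
trial-structured extracellular recordings from delayed-response tasks, and
for the synthetic sessions the package can generate when no recordings are
at hand.

## Who this is for

Systems neuroscientists analyzing multi-unit recordings (e.g. from
high-density probes in prefrontal or parietal cortex) from oculomotor
delayed-response (ODR) experiments: a 1 s fixation, a 0.5 s peripheral cue
at one of eight locations (45° apart), a 3 s memory delay, and a saccade.
The package asks whether delay-period population activity is continuous or
interrupted by coordinated silent / low-information periods, and what those
interruptions do to tuning, behavior, and decodable information.

## The statistics at its core

* **ω² (bias-corrected percentage of explained variance).** For each unit
  and time bin, a one-way ANOVA decomposition over the k = 8 cue locations:

  ω² = (SS_between − df·MSE) / (SS_total + MSE) × 100, df = k − 1 = 7,

  computed on trial counts stratified to the smallest location group.
  Unbiased (centered on 0) under the null; negative values are retained.

* **Preferred location.** The spike-count-weighted circular mean
  T·e^{iθ_pref} = Σⱼ nⱼ e^{iθⱼ} / Σⱼ nⱼ over the 8 cue angles; the modulus
  T ∈ [0, 1] measures tuning concentration.

* **Population ISI statistic for coordinated silences.** For groups of ≥ 5
  delay-selective units sharing a preferred location, spikes are pooled
  within each delay period and the maximum inter-spike interval is
  regressed (log₁₀–log₁₀) on the pooled firing rate across groups.
  Trial-shuffled surrogates (each neuron's trial identity permuted
  independently, 10,000 iterations) give an iteration-matched null
  regression; coordinated silences flatten the empirical slope relative to
  this null (one-sided permutation test, both tails reported).

* **On/off states from decoder confidence.** A lasso-logistic classifier
  (λ = 0.01, leave-one-trial-out, 100 ms bins stepped by 50 ms, z-scored
  rates) separates each location from its diametric opposite; the softmax
  of the class margins gives a per-bin posterior for the trial's true
  location. Against a 50-fold label-shuffle null, z > 1.64 runs whose
  cluster mass beats the 95th percentile of the null max-cluster-mass are
  *on states*; z < 0.3 runs of ≥ 3 bins are *off states*. State-conditioned
  tuning curves are aligned to each unit's preferred location and debiased
  by 1000 label shuffles; labels transfer across simultaneously recorded
  areas (source populations > 80 units).

* **Simultaneous vs. pseudo-population decoding.** 100 pseudo-populations
  splice each neuron's trials within stimulus conditions, preserving
  marginals while destroying within-trial co-fluctuations; the recorded
  session's 8-way decoding accuracy is ranked against theirs per bin and
  summarized per task epoch.

Supporting analyses: beta-mixture (EM) model comparison of delay
confidence via ΔAIC/ΔBIC, Welch spectra of binary state series, and a
session-bootstrapped reaction-time/state effect (β_state = RT_on − RT_off).

## Worked example

```r
library(wmstates)

# a synthetic session: 12 units, 18 trials at each of two diametric cues,
# von Mises tuning (peak/baseline gain 5), coordinated off states during
# which tuning is fully flattened while baseline firing persists
cfg <- sim_config(n_neurons = 12, n_trials_per_location = 18,
                  gain = 5, kappa = 3, seed = 1)
ds  <- simulate_tuned_session(cfg, locations = c(0, 180))
g   <- impose_off_states(ds, multiplier = 0, rate_hz = 0.2, seed = 2)

cn <- confidence_null(g$ds, n_shuffles = 50, seed = 3)  # label-shuffle null
lb <- label_states(cn)                                  # on/off segmentation
state_time_fraction(lb, "off")
#> [1] 0.1883239

st <- state_tuning(g$ds, lb, n_shuffles = 1000, seed = 4)
st
#> <state_tuning> 12 units (0 excluded); mean depth on 0.298, off 0.149; reduction 50.0%
```

The printed summary says: across the 12 units, the aligned, shuffle-debiased
tuning depth (peak minus minimum, in across-trial z-units of firing rate)
during detected on states is 0.298; during detected off states it collapses
to 0.149 — a 50% reduction, recovering the imposed flattening from spikes
alone. The ISI validation harness likewise recovers imposed coordinated
silences from surrogate Poisson cohorts:

```r
h <- isi_validation_harness(seed = 1, n_populations = 50, n_iter = 1000)
h$decisions
#> # A tibble: 2 × 3
#>   cohort          p_flatter detected
#>   <chr>               <dbl> <lgl>
#> 1 without_silence  0.610    FALSE
#> 2 with_silence     0.000999 TRUE
```

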