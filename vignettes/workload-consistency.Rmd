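---
title: "Cross-task consistency of EEG workload indicators: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-task consistency of EEG workload indicators: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probemwl)
```

## The scientific question

Mental workload (MWL) indicators derived from EEG fall into two broad
families. Ongoing-EEG power spectral density (PSD) features -- relative
power in the theta (4--8 Hz), alpha (8--13 Hz), beta1 (13--20 Hz) and
beta2 (20--30 Hz) bands -- index tonic cortical state. Task-irrelevant
auditory event-related potentials (ERPs) -- the N1, early P3a, late P3a
and reorienting negativity (RON) evoked by ignored sound probes embedded
in the task -- index how much attentional capacity the primary task
leaves over. A workload monitor is only useful if its indicator
transfers across tasks: a classifier trained on one task should still
discriminate easy from hard on another. `probemwl` implements a complete
pipeline to compare the two families on exactly this question, on
synthetic recordings whose ground truth is known: the cross-task
consistency of per-feature discriminability, and within-task versus
cross-task classification.

The pipeline has six stages, each exposed as package functions and
driven by the numbered scripts in `analysis/`:

1. **Simulation** (`sim_config()`, `simulate_study()`): multi-channel
   EEG for a 2 task (verbal N-back, MATB) x 2 difficulty (easy, hard) x
   2 block design with auditory-probe event trains.
2. **Preprocessing** (`preprocess_block()`): zero-phase 0.5--45 Hz
   Butterworth band-pass, average-mastoid re-reference, ERP epochs
   (-0.5 to 0.8 s, baseline-corrected on the pre-stimulus mean), 5-s
   spectral epochs centered between consecutive probes, and +/-100 uV
   amplitude rejection.
3. **Features**: single-trial ERP component window means (N1 130--170,
   eP3a 220--270, lP3a 280--350, RON 390--500 ms) and Welch relative
   band powers (1-s Hamming segments, 50% overlap, normalized over
   4--45 Hz).
4. **Discriminant consistency** (`consistency_summary()`): the signed
   Fisher ratio per feature and task,
   $F_{signed} = (m_E - m_H) / \sqrt{\sigma_E^2 + \sigma_H^2}$,
   its absolute between-task difference $|\Delta F_{signed}|$, the
   per-subject mean over features, and a bootstrap paired t-test
   comparing families.
5. **Classification** (`run_suite()`): RBF-kernel SVM, block-wise
   within-task cross-validation and both cross-task transfer
   directions, decision values averaged over n = 1, 5, 10 consecutive
   trials, ROC-AUC scoring.
6. **Statistics** (`boot_paired_ttest()`, `boot_rm_anova2()`,
   `stat_map()`): 1,000-iteration bootstrap tests with
   Benjamini--Hochberg FDR over whole maps and zeroed non-significant
   cells.

## The synthetic EEG generator

Real probe-in-task EEG of this design is not publicly deposited, so the
generator is a first-class part of the package: every downstream claim
is tested against data whose effects are planted and therefore known.

A recording block is the sum of three parts, per channel:

* **Broadband background**: $1/f$ noise (exponent 1, default 10 uV
  RMS), synthesized spectrally and independent across channels.
* **Band-limited activity**: for each of theta, alpha, beta1, beta2, a
  noise process whose power spectrum is the squared magnitude response
  of a 4th-order Butterworth band-pass and whose per-channel variance is
  `base_power * effect(task, difficulty) * topography^2` times a
  per-subject log-normal scale. Each band also carries a slow log-normal
  power drift (SD 0.5 log units, ~10-s correlation time, shared across
  channels, independent between bands). All variances are calibrated
  empirically: each block is rescaled so its realized per-channel band
  variance equals the target exactly.
* **Evoked responses**: at each probe onset, a deterministic template --
  a temporal Gaussian per component, scaled by polarity, base amplitude,
  condition effect and spatial topography. By default there is no
  trial-to-trial latency jitter, which keeps the epoch-averaging oracle
  exact; a `latency_jitter_sd_s` parameter is available for robustness
  experiments.

Probe onsets are i.i.d. uniform 8--22 s apart (so blocks of 600 s carry
about 40 probes); mastoid channels carry pure sensor noise at 10% of
the scalp RMS so that re-referencing is structurally exercised but
nearly a no-op.

### Why the slow band-power drift exists, and why it is ~10 s

Without any nonstationarity, a stationary band-limited process makes
single-epoch relative band power almost noiseless, and PSD
classification becomes unrealistically perfect -- contrary to the whole
premise that ongoing-EEG features are noisy, drifting indicators. The
drift emulates vigilance-like fluctuation of oscillatory power.

Its correlation time matters more than its size. With very slow drift
(minutes), per-trial variance is inflated *within* a block while the
condition mean averages the drift out; the estimated
$\hat F_{signed}$ then has a smaller sampling floor for PSD than for
ERP features, and the mean $|\Delta F|$ comparison between families
acquires a built-in bias that has nothing to do with task consistency.
At a ~10-s correlation time (`drift_cutoff_hz = 0.1`), consecutive
epochs (8--22 s apart) are nearly decorrelated, the two families'
$|\Delta F|$ noise floors match, and the family comparison is driven by
planted task structure alone. This was chosen by explicit diagnostic of
the $\hat F$ sampling distributions and is the package default.

### Scenario presets

* `"paper_like"`: the study conditions. ERP workload effects shrink all
  component amplitudes to 0.6 of their easy value, identically in both
  tasks, except lP3a, which is workload-sensitive only in MATB. PSD
  effects are task-dependent: theta rises with workload fronto-parietally
  in N-back (+30%/-12%) but is nearly workload-insensitive in MATB;
  alpha falls with workload over posterior channels in N-back and
  fronto-central channels in MATB (disjoint masks); beta1 is
  N-back-only; MATB carries global theta-up (x1.4) and alpha-down
  (x0.65) offsets. The magnitudes were fixed so that within-task
  single-trial performance is comparable between families while PSD
  workload effects stay weak, matching the reported pattern that the
  PSD family showed no significant workload main effect and no
  within-task family difference.
* `"null"`: every effect factor is 1 -- no condition information
  anywhere. Used for chance-level and type-I checks.
* `"psd_consistent"`: a control in which the PSD effects use the N-back
  values in both tasks (and ERP effects are fully task-invariant). Used
  to verify that the consistency comparison does not fabricate a family
  difference.

### What the generator does *not* emulate

Volume conduction and channel correlation (channels are independent up
to topography), ocular and muscle artifacts (amplitude rejection exists
but has nothing realistic to reject), probe habituation, ERP latency
variability (unless enabled), task-evoked transients in ongoing EEG,
and electrode impedance drift. Tests passing on this generator
demonstrate that the *analysis machinery* is correct and directionally
faithful; they do not certify performance numbers on human EEG.

## Numerical and procedural choices

* **Filtering**: 4th-order Butterworth high-pass (0.5 Hz) then low-pass
  (45 Hz), each applied forward-backward. The passes run on
  `stats::filter`'s compiled engines with odd-reflection padding; a unit
  test pins the result to `signal::filtfilt` away from the edges.
* **Epoch conventions**: sample ranges are half-open `[t0, t1)` with the
  onset sample on the post-stimulus side: 650-sample ERP epochs and
  2,500-sample spectral epochs at 500 Hz. Spectral epochs are centered
  in the evoked-free interval `[onset_i + 0.8 s, onset_{i+1} - 0.5 s]`,
  one per interval, kept when the interval is at least 5 s (closed
  boundary).
* **Welch settings**: 1-s Hamming segments at 50% overlap give 1-Hz bins
  so the integer band edges land exactly on bins. Band sums are
  half-open (`low <= f < high`); the 4--45 Hz normalization is closed at
  45. A Hamming window leaks ~27% of a pure tone's power into the two
  adjacent bins; tests therefore assert dominance of the exact bin plus
  near-total mass in the 3-bin main lobe.
* **Relative-power modes**: trial mode (normalize each 5-s epoch; used
  for discriminant and classification features) and condition mode
  (average PSDs within subject x task x difficulty, then normalize; used
  for the statistical maps), mirroring the two uses in the source
  design.
* **F_signed**: unbiased (n-1) variances; samples are single trials
  pooled across a condition's two blocks; infinite values (zero pooled
  variance) are excluded from the per-subject mean with a logged count.
* **SVM**: `e1071::svm`, RBF kernel, C = 1, gamma = 1/(d * median
  feature variance of the z-scored training set); features are z-scored
  with training-set statistics only; decision values oriented so
  positive means "hard" (orientation fixed against the training-set
  class means). Within-task cross-validation uses the two blocks as
  folds and averages the fold AUCs.
* **Decision averaging**: chronological, non-overlapping groups of n
  within subject x task x difficulty x block; a trailing remainder is
  kept when it has at least ceiling(n/2) trials.
* **Bootstrap tests**: the null resamples mean-centered paired
  differences (or per-subject effect contrasts for the 2x2
  repeated-measures ANOVA, whose single-degree-of-freedom F equals
  n * mean(c)^2 / var(c)); two-sided p uses the +1 correction so p is
  never 0 and never below 1/(n_boot + 1). Note the interaction of this
  floor with BH-FDR: a map of m cells at q = 0.05 can only reject when
  roughly m/(q * n_boot) cells reach the floor, so map-wide corrections
  need n_boot large relative to m/q.
* **Stat maps**: one FDR family per map; the display copy zeroes
  non-significant cells. Resample indices are drawn independently per
  cell inside one vectorized engine.
* **Determinism**: every randomized stage derives an integer substream
  seed from the master seed and a stream name
  (`substream_seed(master, "sim/s03/matb.hard.b2")`), so subjects,
  blocks and bootstraps are reproducible independently and two runs of
  `run_study()` with the same config produce byte-identical artifacts.

## Problem sizes used by the test suite

The generator defaults are the full study conditions (60 channels,
500 Hz, 600-s blocks, 17 subjects). The automated checks run reduced
instances chosen as the package's own working sizes: the main synthetic
study uses 12 subjects, a 16-channel montage, 200 Hz and full 600-s
blocks (shorter blocks leave too few n = 10 decision groups per fold
for stable AUCs); the task-consistent control uses 50 replicate studies
of 5 subjects at 4 channels and 100 Hz; chance-level classification
uses 20 subjects at 4 channels. All sizes are stated in the tests and
`scripts/acceptance.R` and scale up unchanged.

## Known limitations

* The within-MATB PSD workload effect is deliberately minimal, so
  within-MATB PSD classification is weaker in the simulation than in
  the recorded study; the preset prioritizes the headline contrasts
  (cross-task consistency and transfer).
* Independent channels make topographic structure cruder than real
  volume-conducted EEG; spatial statements should be read as "effect
  present at these channels", not as realistic scalp fields.
* The bootstrap repeated-measures ANOVA follows the standard
  centered-resampling construction and is validated by type-I and power
  simulation, not against any particular published recipe.
* EDF export is minimal continuous EDF (16-bit, 1-s records); it does
  not write EDF+ annotations -- events travel in the companion TSV.
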