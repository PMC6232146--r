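---
title: "Methods: representational similarity analysis of multimodal grasping data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: representational similarity analysis of multimodal grasping data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `grasprsa`.  It is the package's own account of its
science: what each stage assumes, which knobs matter, what the synthetic
generator does and does not emulate, and what passing tests do and do not
show about real recordings.

## 1. The experimental protocol being modelled

A session consists of `n_conditions` grasp types (default 33) presented
in blocks of `n_repetitions` consecutive trials (default 8, so 264
trials).  A trial lasts 15 s: fixation (3 s), observation (4 s),
execution (4 s), relaxation (4 s).  Block order is randomized per
subject.  Modalities and rates: EEG 61 channels at 100 Hz (optionally
1 kHz raw, then filtered and downsampled), EMG 8 channels at 200 Hz,
19 joint angles at a variable 80–120 Hz, and a 3-axis accelerometer at
50 Hz.  `generate_protocol()` encodes this schedule;
`synthesize_session()` realizes it.

## 2. The synthetic-data generator

The generator exists so every downstream stage can be validated against
known ground truth.  It emulates the *statistical structure the analysis
assumes*, not biophysics:

* **EEG.**  Background activity is broadband noise with a first-order
  autoregressive (low-frequency-weighted) component plus ongoing 10-Hz
  and 20-Hz oscillators with random per-trial phase; the exact spectral
  shape is a configuration choice, since only relative power (percent
  change) enters the analysis.  An additional oscillator at the center
  frequency of the *target* frequency neighborhood is present in all
  channels.  From movement onset to the end of the execution phase its
  amplitude is suppressed — an event-related desynchronization.  In the
  five channels of the target channel neighborhood the suppression gain
  is condition specific; everywhere else it is a fixed 0.7.
* **Planting a model RDM.**  The per-condition gains are derived from the
  model RDM by classical multidimensional scaling into (up to) five
  dimensions — one embedding axis per target channel — scaled by
  `effect_size`.  Conditions close under the model therefore receive
  similar suppression profiles, and the ERD/S pattern dissimilarities at
  the target searchlight cell correlate with the model, increasingly so
  with `effect_size`.  At `effect_size = 0` all conditions are
  exchangeable by construction.
* **EMG.**  Execution-phase channel amplitudes are a non-negative synergy
  mixture `weights %*% activation(condition)`; signals are
  amplitude-modulated sinusoidal carriers (distinct frequency per
  channel) so the Hilbert envelope recovers the activation profile.  Rest
  phases carry a small tonic amplitude.
* **Kinematics.**  `angles(t) = rest + basis %*% (scores[condition] *
  m(t)) + noise`, with a 19 × 5 synergy basis, a smooth movement profile
  `m(t)` rising over 0.5 s at onset, and samples drawn at a jittered
  80–120 Hz rate, wrapped to `(-pi, pi]`.
* **Accelerometer.**  Quiescent noise with an abrupt mean-and-slope
  change at the true movement onset (default latency 300 ms after the
  execution cue, Gaussian jitter with SD 50 ms, clipped into the first
  second and flagged).  Onsets are drawn once per session and shared by
  all modalities.
* **Artifacts.**  `inject_artifact_trials()` corrupts chosen trials with
  an observation-phase movement burst or a joint-tracking discontinuity
  (+2.2 rad for 200 ms), both sized to exceed the rejection thresholds.

What it does **not** emulate: eye/cardiac artifacts (cleaning hooks are
identity), electrode drift, volume conduction, realistic EMG spectra, or
biomechanical coupling between joints.  Passing tests therefore show the
*analysis chain* is correct and sensitive, not that it would be free of
artifact-driven confounds on real data.  The effect magnitudes are free
parameters; no fidelity to any particular empirical signal-to-noise ratio
is claimed.

The condition taxonomy (grasp type, thumb position, object shape for each
of the 33 grasps) ships as a plausible synthetic assignment
(`inst/extdata/taxonomy_default_synthetic.tsv`); it is configuration
data, not ground truth, and should be replaced when labelling real
conditions.

## 3. Preprocessing decisions

* **Filtering.**  Fourth-order Butterworth, zero phase
  (forward–backward), 0.1–40 Hz, implemented as a high-pass/low-pass
  cascade with odd reflection padding — numerically stabler than a single
  band-pass when the low edge sits four decades below Nyquist.
* **Downsampling** to 100 Hz uses a symmetric FIR low-pass (cutoff 80% of
  the target Nyquist, exact unit DC gain) and subsampling; zero phase by
  construction.
* **Epoching** cuts 15-s segments at trial-start events and reorders all
  trials to a common ascending condition order.  Incomplete trials are
  flagged, never silently dropped.
* **Movement onset** is detected on the Euclidean magnitude of the three
  accelerometer axes in the first second after the execution cue, as the
  split minimizing the total squared residual of two mean-plus-slope
  segments.  A split is accepted only if it improves the single-segment
  fit by ≥ 10% (relative SSE); minimum segment length is 5 samples; ties
  (a continuous slope break fits either side) resolve to the earliest
  split.  These thresholds are configurable.
* **Trial rejection**: observation-phase smoothed accelerometer magnitude
  deviating > 5 baseline SDs from the fixation mean (task executed too
  early), or any single-step joint-angle jump > 60° (tracking failure).
  The magnitude is smoothed with a 5-sample moving average before
  thresholding so that single-sample noise excursions at rest cannot
  trigger false rejections.  A trial with no detectable onset is also
  rejected, since all feature windows are onset-locked.
* **Morlet TFR**: 0.5-Hz bins over 0.1–40 Hz.  Bin centers start at
  0.5 Hz (the 0.1-Hz band edge lies below the first representable 0.5-Hz
  bin center), giving 80 bins.  The wavelet width is a linearly
  increasing 3–8 cycles across the grid — a standard trade of temporal
  versus spectral resolution; bins whose wavelet (±3 temporal SDs)
  exceeds the epoch are flagged invalid rather than zero-padded silently.
  Wavelets are amplitude normalized (a unit sinusoid at the bin frequency
  has power 1); any fixed normalization cancels in the ERD/S ratio.
* **ERD/S baseline** is the fixation interval 1–3 s from trial start,
  averaged over all trials per subject, per channel and bin.
* **EMG envelope**: each channel is z-scored, then the magnitude of the
  analytic signal is taken.  The phrase "Hilbert transform, z-score,
  envelope" admits several orderings; the implemented order
  (standardize → analytic-signal magnitude) is recorded in the output
  metadata.
* **Kinematics**: cubic-spline interpolation to 100 Hz on unwrapped
  angles (re-wrapped afterwards); per-subject PCA retains 5 components.
  Repetition averaging of raw angles uses the circular mean.  The order
  *circular-mean averaging of angles → projection onto the subject's
  components* is an interpretation (averaging before projection); the
  alternative order differs only through PCA centering and is nearly
  equivalent for small angular spread.
* **Group averaging of kinematic synergies.**  Subject-specific PCA bases
  are not commensurable; each subject's components are aligned to the
  first subject's by greedy maximal-absolute-correlation matching of the
  loadings with sign flipping, then score trajectories are averaged.
  This is a pragmatic choice; a shared group basis would be an
  alternative.

## 4. Searchlight construction

Channel space: the 31 neighborhoods are generated from a serpentine
traversal of a synthetic 2-D 10-10 montage (anterior→posterior rows,
alternating periphery→midline direction), taking cyclic 5-channel windows
with stride 3, so every consecutive pair shares exactly 2 channels.  The
original centroids of the design this emulates are not recoverable; only
the counting and overlap invariants (31 neighborhoods, 5 members, 2
shared) are enforced, and `validate_layout()` rejects any layout —
shipped or user supplied — that violates them.  Because 31 windows × 5
members exceed 61 channels, channels are necessarily reused; windows more
than one step apart may also share members where the traversal wraps.

Frequency space: 5 consecutive bins per neighborhood (a 2-Hz band on the
0.5-Hz grid) with stride 3 bins (1.5 Hz), giving 26 neighborhoods on 80
bins.  The stride is *derived* from "5 members sharing 2"; the
alternative reading (0.5-Hz stride) would give 76 neighborhoods, not 26,
so it is interpreted as the grid resolution.

Patterns concatenate a cell's ERD/S values in fixed order (channel
fastest, then frequency, then time): 5 × 5 × 50 samples = 1250 values per
500-ms window at 100 Hz.  Three consecutive windows from movement onset
cover pre-shaping (0–0.5 s), finalization (0.5–1 s) and holding
(1–1.5 s).

## 5. RSA decisions

* Distances between condition patterns: `1 − Pearson r`; ranking uses
  average ranks on ties; ranks are min–max scaled to [0, 1] (an all-tied
  matrix maps to 0.5).  The raw distance matrix is retained as an
  attribute.
* RDM-to-RDM distance: `1 − Spearman ρ` over the 528 lower-triangle
  entries.  Spearman re-ranks internally, so the comparison is invariant
  to any monotone transform of either RDM — prior rank-scaling is
  harmless and binary categorical RDMs are directly comparable.
* The bootstrap resamples *subjects only* (not trials), with replacement,
  recomputing group patterns → RDMs → region-mean distance per iteration;
  the CI is the percentile interval.  The candidate RDM is held fixed.
  With few subjects the observed value can fall at or outside the
  percentile interval (resampled groups are noisier than the full
  group); such violations are reported, never hidden.  Distances are
  re-ranked within every replicate (ranking after averaging).
* The region of interest defaults to the planted cell and its
  index-adjacent neighbors (a 3 × 3 block of cells); for real analyses it
  should be an explicit list of (centroid, band) pairs in the config.
* The second-level RDM averages the region's rank-scaled reference RDMs
  entrywise into one "eeg_region" representation and relates it to all
  candidate RDMs by rank correlation.  Averaging scaled RDMs is one of
  several defensible summaries; since the second level is again
  rank-based, any monotone-equivalent summary gives the same geometry.
* No inferential machinery beyond bootstrap percentiles is provided (no
  permutation p-values, no multiple-comparison correction across the 806
  cells); the searchlight maps are exploratory.

## 6. Problem sizes used by the test suite

All empirical statements in the tests are computed at these scales,
chosen once as the package's default desk-scale study conditions:

* *Planted-effect recovery*: 20 seeds × (5 subjects, 14 conditions, 1
  repetition, window 1, `effect_size = 1`, noise SD 0.5).  The arg-min of
  the object-shape RSA map must fall on the planted cell or a
  member-sharing neighbor in ≥ 90% of seeds, and the object-shape model
  must be the best candidate at the planted cell.
* *Null calibration*: 4 seeds at `effect_size = 0`; a pooled rank-sum
  test of target-overlapping versus remaining cells must be
  non-significant at α = 0.01.
* *Bootstrap calibration*: a 6-condition, 40-feature, 16-subject
  population with known expected distance (independent Monte Carlo with
  1000 draws); 200 outer cohorts × 200 bootstrap iterations; 95% CI
  coverage must lie in [90%, 100%].
* *Structural checks* run one full 33 × 8 session (264 trials) and a
  2-subject pipeline with the complete 806-cell searchlight.
* *Kinematic variance*: 5 latent synergies, angular noise at 5% of the
  signal SD; the first five components must retain ≥ 95% of variance.

A full 31-subject, 8-repetition cohort is one configuration change
(`grasp_config(n_subjects = 31)`); nothing in the code is specific to the
reduced sizes.

## 7. Known limitations

* The channel montage is a synthetic 2-D projection; neighborhoods are
  ordinal, not geodesic.
* EEG/EMG/kinematic generators share movement onsets but are otherwise
  independent across modalities; cross-modal coupling (e.g. EMG-locked
  EEG activity) is not modelled, so cross-modal similarity in synthetic
  runs arises only through the planted condition structure.
* The ICA-based artifact-correction step of real-data workflows is out of
  scope; the hook is an identity transform because synthetic data are
  generated artifact-free.
* `1 − Pearson` distances are attenuated by measurement noise; group
  averaging before RDM computation mitigates but does not remove this,
  which is why bootstrap replicates sit slightly above the observed
  full-group distance at small cohort sizes.
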