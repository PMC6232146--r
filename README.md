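# grasprsa

Representational similarity analysis (RSA) of multimodal grasping
recordings in R.

## The scientific problem

How the brain represents distinct hand grasps — and which movement
covariates (muscle activity, hand kinematics, or categorical properties of
the grasped object) that representation reflects — can be studied by
comparing *representational geometries* instead of decoding accuracies.
In a condition-rich grasping experiment a participant executes many grasp
types (33 here, in blocks of eight 15-s trials: 3 s fixation, 4 s
observation, 4 s execution, 4 s relaxation) while EEG (61 channels),
8-channel forearm EMG, 19 joint angles and a wrist accelerometer are
recorded simultaneously.

For every measurement modality, condition-specific activity patterns are
turned into a **representational dissimilarity matrix** (RDM): the
33 × 33 matrix of pattern dissimilarities `1 − r` (Pearson), with
off-diagonal entries rank-transformed and scaled to [0, 1].  EEG patterns
are event-related desynchronization (ERD/S) values,

```
ERD/S = (P_movement − P_baseline) / P_baseline × 100%,
```

computed from Morlet time–frequency power (0.5-Hz bins over 0.1–40 Hz)
relative to the fixation baseline, and extracted by a **searchlight** over
31 channel neighborhoods × 26 frequency-band neighborhoods (five members
each, consecutive neighborhoods sharing two members — 806 reference RDMs
per 500-ms analysis window).  Candidate RDMs come from EMG Hilbert
envelopes, kinematic principal-component synergies, and binary categorical
models (grasp type, thumb position, object shape).  Reference and
candidate RDMs are compared with `1 − Spearman ρ`; uncertainty comes from
a subject-level bootstrap, and a second-level RDM of RDMs relates all
representations to each other.

`grasprsa` implements this entire chain, together with a synthetic
multimodal session generator that emulates the protocol and plants a known
condition-similarity structure at a known searchlight cell, so the whole
pipeline is testable end to end without any external data.

## Worked example

A reduced synthetic cohort (3 subjects, 14 conditions, 2 repetitions) with
the object-shape model planted in the lower-beta band over the
centro-parietal neighborhood:

```r
library(grasprsa)
cfg <- grasp_config(n_subjects = 3, n_conditions = 14, n_repetitions = 2,
                    seed = 42, windows = 3, n_boot = 200)
result <- run_pipeline(cfg)
summary(result)
#> Per-window RSA summary
#>   window best_candidate_region region_mean best_candidate_global
#> 1      1          object_shape       0.582          object_shape
#> 2      2          object_shape       0.575          object_shape
#> 3      3          object_shape       0.573          object_shape
#>   argmin_channel_nb argmin_freq_nb min_distance boot_candidate boot_observed
#> 1                14             10        0.310   object_shape         0.582
#> 2                14             10        0.313   object_shape         0.575
#> 3                14             10        0.310   object_shape         0.573
#>   ci_low ci_high
#> 1  0.571   0.667
#> 2  0.548   0.637
#> 3  0.545   0.606
#>
#> Trials rejected: 0
#> Localized representational structure at the window-1 arg-min (rank-sum p = 0.00019)
#> Planted-effect recovery: arg-min hits the planted cell/neighbors; best model object_shape (planted object_shape)
```

Reading the output: in every 500-ms window the candidate RDM closest to
the EEG reference RDMs in the region of interest is the object-shape
categorical model (mean `1 − Spearman` distance ≈ 0.58, bootstrap 95% CI
in brackets), and the cell with the overall minimum distance
(`argmin_channel_nb` 14, `argmin_freq_nb` 10) is exactly the cell where
the effect was planted — the pipeline localizes and identifies the
planted representation.  `plot(result$rsa_maps[[1]]$object_shape)` draws
the channel × frequency distance map; `plot(result$candidate_rdms[[1]]$emg)`
draws an RDM.

## Package tour

| Area | Functions |
| --- | --- |
| Protocol & taxonomy | `generate_protocol`, `default_taxonomy`, `validate_taxonomy` |
| Synthesis | `synthesize_session`, `synthesize_eeg`, `synthesize_emg`, `synthesize_kinematics`, `synthesize_accelerometer`, `inject_artifact_trials`, `effect_spec` |
| Preprocessing | `bandpass_filter`, `downsample`, `epoch_trials`, `detect_movement_onset`, `reject_trials`, `morlet_tfr`, `compute_erds`, `emg_envelope`, `interpolate_kinematics`, `circular_mean`, `kinematic_pca`, `average_condition_patterns` |
| Searchlight | `searchlight_layout`, `build_channel_neighborhoods`, `build_frequency_neighborhoods`, `validate_layout`, `extract_pattern` |
| RSA | `compute_rdm`, `categorical_rdm`, `compare_rdms`, `searchlight_rsa`, `bootstrap_effect`, `second_level_rdm` |
| Pipeline & I/O | `grasp_config`, `run_pipeline`, `summary`, `write_session`, `read_session`, `write_rdm`, `write_qc_report` |

The methods vignette (`vignettes/grasp-rsa-methods.Rmd`) documents the
model assumptions, parameter choices, numerical decisions and the scales
at which the test suite runs.
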