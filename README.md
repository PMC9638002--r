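# ethospike

Spike-train and behavior analysis for ethological-event electrophysiology.

`ethospike` implements the analysis pipeline for extracellular recordings
taken while an implanted rat freely interacts with ethologically relevant
stimuli — male and female conspecifics, a moving toy, food — in repeated
5-min baseline / 5-min event / 5-min post blocks. It is aimed at systems
neuroscientists working with basolateral-amygdala-style datasets: sorted
Neuropixels units, an event schedule, pose tracking of both animals, and a
random-pulse video–ephys synchronization channel. Because such recordings
are typically available only on request, the package ships a first-class
synthetic-session generator whose ground truth exercises (and tests) every
stage of the pipeline.

## What it computes

- **Session handling** (`read_session`, `write_session`, `validate_session`):
  a plain-text, inspectable session layout; `align_sync` maps video frames
  onto the ephys clock from an 80%-random pulse code;
  `refractory_violation_fraction` implements the < 0.1% @ 2 ms unit-QC rule.
- **Response scoring** (`score_session`, `response_score`, `classify_unit`):
  per-event response score `s = 2·(auROC − ½)`, where the auROC compares
  1-s event firing-rate bins against the preceding baseline (midrank ties;
  units with < 50 pooled spikes score 0). Class averages above +0.2 define
  event-specific, multimodal (panresponsive when both social and non-social
  classes respond), decreased (below −0.2) and nonresponsive units.
  Population response vectors are compared by Pearson correlation
  (`population_correlation`) and anatomical clustering by mean pairwise
  depth distance (`pairwise_depth_stat`).
- **Temporal dynamics** (`zscore_psth`, `timewarp`, `onset_synchrony`,
  `detect_aftereffects`): 100-ms PSTHs z-scored to each event's baseline;
  cubic-spline time-warping into a common presentation→contact frame;
  latency-to-peak synchrony within vs across events (Kolmogorov–Smirnov);
  aftereffects flagged when mean 10-s-bin z exceeds 1 over the 3 min after
  stimulus removal.
- **Behavior** (`clean_tracking`, `compute_features`,
  `train_behavior_classifier`, `postprocess_bouts`, …): likelihood
  thresholding (0.999 colored / 0.9 other) with linear interpolation;
  30 pose features; a 7-class rbf-kernel SVM frame classifier with 5-fold
  and leave-one-recording-out validation; bout cleanup (merge gaps
  < 0.25 s, drop runs < 5 frames); contact thresholds for toy/food
  sessions; interaction-gated auROC scores; peri-bout histograms (|z| > 5);
  firing–speed cross-correlation at 50 ms.
- **Connectivity** (`cross_correlogram`, `detect_connection`,
  `connection_strength`, `connection_type_enrichment`): 0.25-ms-bin
  cross-correlograms over ±50 ms; a directional putative monosynaptic
  connection is a peak in (0, 5) ms exceeding the noise mean by 3 SD with
  half-prominence width ≥ 0.75 ms and a left edge at or after 0 ms
  (≥ 100 spikes per train, peak ≥ 20 counts). Strength = spikes inside the
  detected peak / target spikes in the epoch; enrichment over chance by
  1000× category-label shuffling.
- **Decoding** (`loo_stimulus_decoder`, `neuron_dropping_curve`,
  `window_decoder`, `interaction_decoder`): leave-one-out linear
  discriminant analysis on population response-score vectors with
  500-shuffle controls, neuron-dropping and category-omission analyses,
  peri-contact sliding-window decoding, and binary interaction/movement
  decoding summarized as ROC areas.
- **Waveforms** (`waveform_metrics`, `cell_type_clusters`,
  `match_units_across_days`): trough-to-peak cell typing by 2-means;
  cross-day unit matching by windowed structural similarity (SSIM) of
  centered 20-channel waveform heatmaps with per-channel correlations.
- **Synthetic sessions** (`sim_config`, `simulate_session`,
  `simulate_tracking`, `inject_connection`, `simulate_two_day_waveforms`):
  inhomogeneous-Poisson units (2-ms dead time) with λ(t) = baseline ×
  gain(t) — low median baselines (0.5 spikes/s), 3–6× event gains starting
  between presentation and first contact, panresponsive on/off transients,
  exponential aftereffects — plus millisecond-latency pairwise coupling,
  scripted two-animal behavior bouts, and drifting-clock sync pulses, all
  with exported ground truth.

## Worked example

```r
library(ethospike)

cfg <- sim_config(n_units = 30, seed = 42)
sim <- simulate_session(cfg)
scoring <- score_session(sim$session)
table(scoring$profiles$category)
#>       decreased female_specific   food_specific   male_specific   nonresponsive
#>               2               2               2               2              17
#>   panresponsive    toy_specific
#>               3               2
mean(scoring$profiles$category == sim$truth$units$category)
#> [1] 1   # every unit's true category recovered at the default 3-6x gains

proj <- simulate_poisson_train(10, 600)
targ <- merge_spike_trains(simulate_poisson_train(4, 600),
                           inject_connection(proj, delay_ms = 1.5,
                                             transfer_prob = 0.15))
ccg <- detect_connection(cross_correlogram(proj, targ))
c(ccg$significant, ccg$peak_lag_ms)
#> significant at a 1.12-ms lag; connection strength
#> sum(ccg$counts[ccg$peak_bins]) / length(targ) = 0.291
```

The category table says 13 of 30 simulated units respond to at least one
stimulus class (the rest are nonresponsive or decrease firing), and the
classifier's labels match the generator's ground truth unit for unit. The
detected cross-correlogram peak sits ~1 ms after the projection spike —
the signature of a putative monosynaptic connection — and roughly 29% of
the target's spikes fall inside it, the injected transfer probability plus
chance coincidences.

## Analysis workflow

Numbered drivers under `analysis/` run the full pipeline on a reference
synthetic session and write tables under `results/` (the bulky session
directory goes to `scratch/`):

1. `01_simulate_session.R` — build and QC the session (50 units, 8 events).
2. `02_response_scoring.R` — scores, categories, population correlations,
   depth clustering.
3. `03_temporal_dynamics.R` — warped traces, onset synchrony, aftereffects.
4. `04_behavior.R` — features, classifier cross-validation, bouts, contact
   threshold, interaction and speed responses.
5. `05_connectivity.R` — connection scan vs injected truth, enrichment,
   epoch-wise strength.
6. `06_decoding.R` — stimulus/window/interaction decoding reports.
7. `07_waveforms.R` — cell typing and cross-day matching.

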