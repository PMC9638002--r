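---
title: "Methods: models, parameters and design choices in ethospike"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in ethospike}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ethospike` analyzes extracellular recordings made while an implanted rat
freely interacts with ethological stimuli (male/female conspecifics, a
moving toy, food) in repeated baseline–event–post blocks. This vignette
documents the statistical models the package implements, the parameters
that matter, the synthetic-data model that stands in for the recorded
sessions, and the design decisions taken where the methods left room.

## Session model and time base

All analysis runs on the ephys clock in seconds; video frames are mapped
onto it once by `align_sync()` and never converted again. Every analysis
window is half-open `[start, end)`. An event block carries five anchors —
baseline start, stimulus presentation, first direct contact, stimulus
removal (event end), post end — with nominal 300-s baseline and event
spans. Sorted single units are the package's input boundary: upstream
spike-sorting QC (waveform amplitude, 50-Hz noise) is assumed done, and
the package re-checks only the refractory criterion (fraction of
inter-spike intervals below 2 ms must stay under 0.1%), because that is
the one criterion computable from spike times alone.

`align_sync()` exploits the acquisition design in which each frame has an
80% chance of emitting a TTL pulse: frames whose pulse was sent are pinned
to their received times; withheld frames are interpolated between
neighboring pulses by frame index (equivalently, at the locally estimated
frame period), and frames outside the pulse span are extrapolated at the
nominal period. With all pulses sent the mapping is exact for any monotone
clock; with the 80/20 pattern the error is bounded by one frame period
under bounded clock drift.

## Response scoring

Firing is binned at 1 s over the 5-min event and its immediately preceding
5-min baseline. The response score is `2·(auROC − 0.5)`, where the auROC
treats event bins as the positive class and is computed through the
rank-sum identity with midrank tie handling — so the score equals the
brute-force "pairs won plus half the ties" statistic exactly, which the
test suite verifies against an independent pair-counting oracle at 1e-12.
Units with fewer than 50 spikes pooled over the two periods are assigned
score 0; the pooled reading of the 50-spike rule was chosen over a
per-period one as the simplest consistent interpretation (a per-period
variant is a one-line change in `response_score()`).

Class scores average over all presentations of a class. The category rules
at threshold θ = 0.2: exactly one class above θ gives the event-specific
category; two or more spanning the social (male/female) and non-social
(toy/food) sides give `panresponsive`; two or more on one side give
`multimodal_social`/`multimodal_nonsocial`; none above θ but at least one
below −θ gives `decreased`; otherwise `nonresponsive`. Multimodal units
count as responsive for population vectors and decoders.

## Temporal dynamics

PSTHs use 100-ms bins z-scored to the same event's baseline mean and SD.
Degenerate baselines are handled explicitly: an entirely silent baseline
yields z = 0 wherever the rate is 0, and any non-zero rate is scored
against an SD floor equal to the SD a single baseline spike would produce
(`(1/bin_s)/sqrt(n_baseline_bins)`), avoiding infinities on the very
low-rate units this preparation is full of.

Time-warping cuts each trace at the presentation and contact anchors
(snapped to the nearest bin center so the anchors are interpolation knots)
and resamples the three segments by natural cubic splines to fixed lengths
— 50/100/50 samples by default; the common-frame lengths are not dictated
by the method and are configurable. Anchor values are preserved exactly
and collinear segments stay collinear. Warped traces serve visualization
and averaging only; all quantification runs on the raw unwarped z data.

Latency to peak is the argmax of the z trace between presentation and
contact after a 1-s boxcar smooth, ties broken to the earliest bin — the
smoothing suppresses single-bin Poisson argmax jitter at sub-spike-per-bin
rates. Within-event onset distances pair different units in the same
trial; across-event distances pair the same units across trials; the two
sets are compared by a two-sample Kolmogorov–Smirnov test
(`stats::ks.test`).

Aftereffects: for each responsive unit and each event of its driving
class, firing after stimulus removal is z-scored in 10-s bins against the
same event's baseline and averaged over a 3-min horizon. The unit/event is
flagged when that mean exceeds 1. The method's phrasing supports either a
per-bin proportion or a per-unit mean; the mean was chosen as the
unit-level flag (with the per-bin flagged-proportion curve also emitted),
because it gives a single well-defined decision per unit/event. Unit-level
flags average over the unit's analyzed events.

## Behavior

Tracking points below likelihood 0.999 (experimenter-colored parts) or 0.9
(others), and points anatomically implausibly far from their skeleton's
per-frame median (default 12 arena units), are removed and refilled by
linear interpolation per body part. Thirty per-frame features are
computed: per-animal head/tailbase speeds, spine length, head angular
velocity and 1-s-offset tailbase speed; matched-part inter-individual
distances (head, tailbase, nape, back) plus the two head-to-tail
distances; head-direction angles from each animal to four of the other's
parts; head-angle difference; head–head minus head–tail differences in
distance and head direction; a centered 1-s head-position correlation;
relative head speed; centroid distance. The exact body-part
parameterization of the feature list is under-specified in the source
methods; the named parts are implemented literally and the remainder
documented here as the package's choice. Gross outliers (beyond 10 MADs)
are removed and interpolated, mirroring the stated outlier-removal step;
angles are wrapped to (−π, π].

The frame classifier is an rbf-kernel SVM (`e1071::svm`, standardized
features) over the 7 labels, validated both by 5-fold and by
leave-one-recording-out cross-validation. Bout cleanup merges same-label
runs separated by a single intervening run shorter than 0.25 s (the quoted
"0.25 ms" gap is read as 0.25 s — a 30-Hz video cannot resolve 0.25 ms),
then dissolves non-background runs shorter than 5 frames into the
background class; the merge-then-delete sweep iterates to a fixed point,
making the operation idempotent. Contact thresholds for toy sessions
maximize balanced accuracy of contact vs no-contact over the social-frame
distances ("optimal threshold" is otherwise unspecified); food sessions
use a region-of-interest polygon (`pracma::inpolygon`).

Interaction responses reuse the auROC score on 1-s bins split by the
interaction mask within each event's post-contact span, averaged over the
unit's responsive events and classified at ±0.2. Peri-bout histograms
average ±5 s around bout onsets in 100-ms bins, z-scored to the [−5, −2) s
window (the "first 3 s" of the window), flagging |z| > 5 after onset.
Speed correlations use 50-ms bins, `stats::ccf`, epoch-averaged profiles,
and classify by the lag-0 value against the mean over lags −20…−10 s with
a 2-SD noise band; "none" is returned inside the band.

## Connectivity

Cross-correlograms count target-minus-projection lags in 0.25-ms bins over
±50 ms. Noise statistics come from the bins with |lag| in (5, 50] ms —
the method does not say which bins define its mean and SD, and this choice
excludes the putative synaptic window while keeping ample mass. Detection
searches (−5, +5) ms for local maxima exceeding the noise mean by 3 SD,
measures width at half-prominence by linear interpolation (half level
midway between peak height and noise mean; the left crossing is the peak
onset), and retains a peak only if the width is at least 0.75 ms, the lag
is positive and the onset does not start before 0 ms. Pairs with under
100 spikes in either train, or a tallest bin under 20 counts, are
excluded; the 20-count minimum is read as the single tallest bin
(configurable), the most plausible reading of "peak firing". The zero-lag
bin is counted but a peak exactly at lag 0 is rejected by the positivity
rule. The 3-SD-plus-width rule's false-positive rate on independent
Poisson pairs is calibrated in the acceptance suite (≤ 2% at 600-s
trains, rates 1–10 Hz): the width criterion is what rejects single-bin
Poisson excursions.

Connection strength is the number of spikes inside the detected peak's lag
extent divided by the target's total spikes in the epoch. Epoch-wise
analyses recompute the CCG and its noise statistics on the
epoch-restricted trains — shorter epochs carry larger SDs, so per-epoch
significance is conservative by construction. Enrichment of connection
types over chance divides observed (projection category → target category)
counts by their mean under 1000 seeded permutations of category labels
over the observed projection and target node sets. Per-pair strength
changes between consecutive epochs use a paired t test.

A note on the synaptic jitter: with 0.25-ms bins, a ±0.25-ms uniform
transmission jitter would concentrate a connection's CCG mass in about two
bins, and no such peak can pass a 0.75-ms width criterion — the width rule
and a sub-bin jitter are mutually exclusive. The generator therefore uses
a ±0.5-ms uniform jitter (`inject_connection(jitter_ms = 0.5)`),
consistent with in-vivo monosynaptic latency SDs of roughly 0.3–0.6 ms,
which yields ~1-ms-wide peaks that the width rule accepts while single-bin
noise is rejected.

## Decoding

All decoders are linear discriminant analyses (`MASS::lda`) behind a
shared preparation: features are standardized with training-fold
statistics and projected onto at most `n_train − n_classes` principal
components before fitting, which keeps the within-class covariance
nonsingular when units outnumber events (inevitable here); priors are
uniform so that shuffle controls center on analytic chance. Stimulus
identity is decoded from per-event population response-score vectors with
leave-one-out folds and 500 label-shuffle controls; neuron-dropping curves
resample unit subsets (500× per size by default); category omission
compares the omitted-category accuracy against random subsets of matched
size. The peri-contact window decoder recomputes response scores in 10-s
windows sliding −30…+30 s around first contact; the within-event
timecourse decoder does the same in 10-s bins from 2 min before event
start to 2 min after event stop, testing per-bin vectors against a decoder
trained on full-event scores. Binary interaction/movement decoding uses
5-fold cross-validation on per-bin z-rate population vectors and reports
the ROC area of held-out decision scores.

Calibration note: leave-one-out with permuted labels is negatively biased
at very small samples — holding out an event leaves one training exemplar
of its class when there are only two presentations per class, and the
deficient class's noisier centroid loses assignments. The package's
decoding analyses therefore run on sessions with four presentations per
class (16 events), within the recorded design's range (social stimuli were
presented 2–4 times each and the battery repeated), where the control
converges to 1/4 within the acceptance band. The generator's default
battery remains two presentations per class.

## Waveform analyses

Cell typing takes the trough-to-peak delay on the peak-amplitude channel
(trough = global minimum, peak = subsequent maximum; positive-first
waveforms are `irregular` and excluded) and the baseline rate from the
day's first 5 min, standardizes both axes, and splits units by 2-means
with a seeded multi-start; the longer-delay cluster is labeled putative
pyramidal.

Cross-day matching compares per-unit heatmaps of the normalized mean
waveform over 20 consecutive channels centered on the unit's channel
(zero-padded at array edges, normalized by absolute peak). Candidates are
day-2 units within ±5 channels. Similarity is the windowed SSIM (mean
local SSIM over 7×7 patches, the standard image-similarity definition):
local windows weight the small-amplitude off-center structure that
actually distinguishes nearby units, where a single global window is
dominated by the shared trough-peak shape. The secondary statistic is the
per-channel Pearson correlation weighted by the day-1 template's
per-channel amplitude, so channels carrying no waveform do not dilute it.
Assignment is greedy one-to-one by similarity; acceptance requires
similarity ≥ 0.3 (on the windowed-SSIM scale, chosen so that
noise-limited true matches pass) and weighted correlation ≥ 0.7. The
false-acceptance calibration uses structure-free random waveforms (smooth
random traces under a spatial envelope): with cohorts drawn from the same
spike-template distribution, a fraction of units acquire unrelated
near-twins inside the noise ball, and no pairwise statistic can separate
those — which is why the original procedure relied on visual
verification.

## The synthetic-session generator

`simulate_session()` is the package's oracle: every downstream stage is
tested by recovering its ground truth. Units are inhomogeneous-Poisson by
thinning with a 2-ms absolute dead time (so the cohort passes the
refractory QC that real curated units meet), with rate λ(t) = baseline ×
gain(t):

- baseline rates are log-normal with median 0.5 spikes/s (σ_log = 0.5),
  matching the low resting rates of event-specific units; panresponsive
  units use a higher median (2 spikes/s), and a 20% interneuron fraction
  multiplies baselines 8×;
- event gains are drawn uniformly from 3–6 and switch on at a per-trial
  onset drawn uniformly between presentation and first contact. The onset
  is common to all responsive units within a trial up to a 0.5-s Gaussian
  per-unit jitter — the construction that makes within-event latencies
  tighter than across-event ones, as the onset-synchrony analysis assumes;
- panresponsive units add a +3× additive transient for 2 s at
  presentation and removal (amplitude and duration are free parameters,
  not claims — the source does not quantify them);
- an exact 30% of responsive units (rounded count, randomly allocated)
  carry aftereffects: gain decays as `1 + (g−1)·exp(−t/τ)` with τ = 120 s
  after removal, truncated at the next block's start so ground truth stays
  unambiguous;
- `decreased` units use gain 0.2 during one class;
- category counts follow the configured mix exactly (largest-remainder
  allocation), so recovery criteria measure classification error, not
  composition sampling noise;
- pairwise coupling superimposes induced spikes at `delay + U(−0.5, 0.5)`
  ms with the configured transfer probability;
- sync pulses follow the 80% random pattern under a small clock offset
  and drift (2×10⁻⁵ relative).

`simulate_tracking()` scripts the seven behavior labels geometrically
(snouts facing and ~1 cm apart for head-to-head; implanted just behind
the tailbase for head-to-tail; aligned co-motion 16 cm apart for
following, clearly beyond the near-contact geometries; approach restarts
22 cm out and closes on a stationary conspecific), separated by
non-social stretches scaled to a 60% non-social frame fraction, with
0.3-cm coordinate noise and 3% i.i.d. likelihood dropouts. Waveform
templates carry eight shape/spatial parameters per unit (trough/peak
widths, amplitude ratio, pre-trough bump, sub-channel offset, spatial
asymmetry, propagation lag) — the between-unit variability that makes
real units distinguishable across days.

What the generator does **not** emulate: oscillations, bursting,
non-Poisson interval statistics, rate nonstationarity within epochs,
electrode drift within a day, correlated noise across units, occlusion
structure in tracking failures (dropouts are i.i.d.), and identity
differences among individual conspecifics. Passing tests therefore show
that each method recovers the effects it targets under its own stated
noise model — not that it is robust to every artifact of real recordings.

## Problem sizes and numerical conventions

The test and acceptance suites run at desk scale, chosen so the full suite
completes in a few minutes: 200-unit cohorts for category recovery,
50-unit/600-s sessions with 20 injected connections (plus 1000 independent
pairs for false-positive calibration), 100-unit cohorts for aftereffects
and cross-day matching, 24-unit cohorts for onset synchrony, 60-unit
16-event sessions for decoding, and 10-min tracking simulations (4000
sampled frames) for behavior. Spike times are double-precision seconds;
session files store floats at 17 significant digits so write/read round
trips are bit-exact. Ties break deterministically everywhere (earliest bin
for latency peaks; highest-then-smallest-lag for CCG peaks; first-of-burst
for dead-time deletion), and every stochastic routine takes an explicit
seed.

## Known limitations

- Epoch-wise connection significance loses power on low-rate projections
  (a 0.5-Hz unit fires ~150 spikes in a 300-s epoch, near the 100-spike
  floor), so epoch tables are sparser than whole-session scans — visible
  in the analysis drivers.
- The latency-to-peak estimator is meaningful only for units with a
  sustained event response; flat traces are skipped with a log entry.
- Inhibitory (trough-type) cross-correlogram connections are out of scope,
  as are jitter-corrected spike-transmission models.
- The behavior classifier's residual errors concentrate at bout
  transitions, where 1-s-context features necessarily straddle two labels.
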