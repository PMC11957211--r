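---
title: "Methods: neural and facial trajectory analysis of stress-induced anhedonia"
author: "valenceDynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neural and facial trajectory analysis of stress-induced anhedonia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Chronic mild stress produces anhedonia — a reduced capacity for pleasure —
in some animals (susceptible) but not others (resilient), even among inbred
littermates. This package implements a longitudinal analysis of that
individual variability in a head-fixed Pavlovian discrimination experiment:
mice learn that a 9-kHz tone predicts sucrose and a 2-kHz tone predicts an
air puff, while medial prefrontal cortex (mPFC) populations are imaged with
two-photon calcium microscopy (~29.8 Hz) and the face is filmed for
markerless keypoint tracking. The analysis asks three questions:

1. **Phenotyping.** Can stressed mice be separated into resilient and
   susceptible groups from their sucrose-preference scores alone?
2. **Neural geometry.** Does the ratio of reward-evoked to punishment-evoked
   population dynamics change differently over stress and ketamine
   treatment in control versus stressed animals?
3. **Decoding.** Can phenotype be predicted — before stress ever starts —
   from single-trial neural or facial responses?

Because the corresponding raw animal data are not publicly deposited, the
package ships a synthetic cohort generator that emulates all four raw data
streams (behavioral scores, trial/lick tables, neuron-by-frame activity
with cross-session cell identity, and 13-point facial keypoint tracks) with
planted, configurable effects. Every analysis stage is exercised end to end
against that generator's ground truth.

# Behavioral phenotyping

Sucrose preference is `sucrose licks / (sucrose + water licks) x 100`.
Stressed mice are clustered on their post-stress preference with seeded
k-means (at least 50 random restarts, best within-cluster sum of squares
kept); clusters are mapped to phenotypes purely by their mean preference —
lowest mean is susceptible, highest resilient, the middle cluster (k = 3)
neutral. Control mice never enter the clustering: the source protocol is
ambiguous on this point, and we treat non-stressed animals as a fixed
reference group.

## The elbow rule

The cluster count is chosen by the "optimal k elbow" on the WCSS curve.
No exact formula for the elbow exists in the protocol, so the rule is a
documented package choice: WCSS values are cube-root transformed — the
Wilson–Hilferty transform, which stabilizes the variance of sum-of-squares
quantities — both axes are rescaled to the unit interval, and the selected
k is the interior point lying furthest below the straight line joining the
first and last curve points (the classic knee heuristic). On the raw scale
the frequently quoted "maximum second difference" rule is dominated by the
k = 1 to 2 drop and collapses to k = 2 on almost any multi-cluster data;
on the stabilized scale the knee recovers the planted k in ≥ 99% of
simulations with three groups at 55/75/90 ± 4 percentage points (n = 24),
and equally reliably recovers two or four planted groups. The raw
second-difference rule remains available via
`selectKElbow(w, method = "curvature")`. Ties break toward the smallest k,
so a perfectly linear WCSS decline yields the first interior k.

With group separations below roughly five within-group standard deviations,
exact label recovery (adjusted Rand index of 1) cannot be expected on every
draw — at the 55/75/90, sd 4 condition about half of simulated cohorts have
at least one boundary mouse on the wrong side — which is why the recovery
tests quote exact recovery only at ≥ 5-sd separation.

# Lick behavior and social geometry

Lick PSTHs report, per peri-CS bin, the fraction of trials with at least
one lick (a probability, not a normalized lick count — the two readings are
both defensible, and the probability reading matches the quantity name).
Window probabilities default to the anticipatory (0–2 s, CS onset to US
delivery) and consummatory (2–5 s) windows. Correlations with sucrose
preference use Pearson's r with the two-sided t-transform p-value.

The social-interaction rule counts a frame when the nose is within 1.3
cup radii of the cup center *and* the animal faces the cup. "The angle
between the subject's nose, body, and the center of the cup" leaves the
vertex ambiguous; we place it at the nose — the angle between the
body-to-nose direction and the nose-to-cup direction — because that is a
facing criterion, which matches the stated intent of interaction detection.
`vertex = "body"` is available as the alternative reading.

# State-space trajectories

Event-aligned tensors hold units x 100-ms bins x trials over −10..+10 s
around an event; bins are half-open `[t, t + 0.1)` and bin centers are
reported. Two normalizations are used, mirroring the two figure families:

* **local z-score** — each unit on each trial is normalized to that trial's
  own pre-event baseline. The neural baseline window is not stated in the
  protocol; the default is the full −10..0 s pre-event window,
  configurable. The facial baseline is fixed at the stated 5 s immediately
  preceding the trial.
* **super-global z-score** — for ROI-matched cells compared across two
  sessions, each cell's full trace is normalized by the mean and sd pooled
  over the concatenated sessions. The source phrase ("normalized across
  multiple sessions") admits a baseline-only reading; pooled-session
  moments were chosen as the plainer reading.

One PCA is fit per analysis on a units x columns matrix of mean z-scored
responses (columns concatenated over events, groups and weeks), with each
unit centered by its mean over the training columns and no variance
scaling — the inputs are already z-scores, and this centering convention is
the one under which "coefficients times mean response" reconstructs the
data. The same coefficients are then used for every projection within the
analysis (trajectories across weeks, leave-one-out iterations, single
trials); the PCA is never refit per condition.

Trajectory length is the sum of Euclidean distances between adjacent bins
(quantified post-event over 0–10 s unless stated); trajectory distance is
the bin-by-bin Euclidean distance. Quantification dimensionality follows a
variance-fraction rule — the smallest number of leading components
capturing 60% (neural) or 90% (facial) of the variance — generalizing the
data-specific component counts quoted in the source (23 PCs / 59.51% and
8 PCs / 90.54%); both are overridable. Facial "trajectory norms" are read
as path lengths, consistent with the neural definition.

Group statistics use leave-one-animal-out resampling: one iteration per
held-out mouse, each iteration projecting the remaining animals' units with
the same fixed coefficients. Neuron counts can be matched across groups by
seeded uniform subsampling to the smallest group.

## The reward/punishment ratio

For each mouse, the cells tracked across a pair of time points are
super-global z-scored across the two sessions, aligned to the reward and
punishment US, and projected into a PC space fit once on the pooled matched
population of all mice. The per-epoch ratio is the reward trajectory length
over the punishment trajectory length (0–10 s post event), and the
normalized change is the second epoch's ratio over the first's. The ratio
is computed per mouse — the granularity is not stated in the source, but
its paired statistics across subjects require per-mouse values. Punishment
lengths of zero raise an explicit error rather than returning infinities.

# Facial features

Keypoint tracks (frames x 13 nodes x x/y/confidence) are gap-filled by
linear interpolation wherever confidence falls below 0.5 (threshold not
stated in the source; 0.5 is the conventional cut for pose-track
confidence), smoothed with a Savitzky–Golay filter over a 5-frame window
(polynomial order 2 — unstated, and order 2 is the lowest that preserves
curvature), and calibrated from the imaged sucrose-spout length to
centimeters.

The exact feature registry of the original extractor is not enumerated, so
the default registry is versioned and documented: all 78 pairwise
distances among the 13 nodes (cm); six interior angles (degrees, vertex at
the middle node, reported in [0, 180]): the two eye corners, nostril flare,
nose bridge, mouth opening and whisker spread; speed and acceleration
magnitudes of the nose tip and the eye centroid (central differences
scaled by the frame rate; one-sided at the series ends); and the shoelace
areas of the eye, nose and mouth polygons (cm²). That is 91 channels with
stable names, kinds and units. Distances, angles and areas are invariant
under rigid motion of the camera frame; kinematics under translation.

The facial difference score aligns every trial of one type to CS onset,
normalizes it to its own 5-s pre-trial baseline, trial-averages, projects
through a PCA fit once on the pooled responses of all subjects (feature
channels are shared across subjects, unlike neurons), and reports the
post-event path length (0–10 s) minus the pre-event length (−10..0 s).
The pooled fit follows the "total feature set across all sessions"
phrasing; a per-session refit is a caller-side option since the model
input is explicit.

# Decoding

Samples are per-trial PC coordinates per time bin: a single PCA is fit on
the pooled trial-mean responses, and each individual trial is projected
through its own subject's loading rows. The per-session-per-week feature
granularity of the source is ambiguous; per-trial samples were chosen
because they make 10-fold cross-validation well-posed.

The classifier is a logistic model — binomial for pairwise comparisons,
multinomial for the three-way facial decoder — fit by glmnet with a small
fixed L2 stabilizer (`lambda = 1e-3`, `alpha = 0`): the source specifies a
GLM with no regularization, and the ridge term exists only to keep
separable bins numerically defined while leaving the fit effectively
unpenalized. Folds are stratified by class and seeded; performance is the
area under the ROC curve on the held-out fold (macro-averaged one-vs-rest
for three classes). The shuffled-label null permutes labels globally
*before* the CV split (the source does not state whether shuffling
preserved folds; the global permutation is the stricter null), with
permutations seeded independently of folds. Empirical p-values use the
standard `(1 + #{null ≥ observed}) / (1 + n_perm)` construction.

AUC time courses can be smoothed with a strictly causal Gaussian moving
average over the trailing 20 s; the Gaussian sd is not stated and defaults
to one third of the window, with weights renormalized where the window is
truncated at the series start.

# The synthetic cohort generator

The generator is the package's stand-in for the raw experiment and defines
the study conditions of every planted-effect test:

* **Timeline and design.** Ten weekly epochs (baseline, six stress weeks,
  saline, ketamine, post-ketamine); acquisition sessions of 36 reward,
  2 reward-catch, 8 punishment and 2 punishment-catch trials, 5-s CS, 2-s
  US delay, 25–30 s ITIs, 9/2 kHz tones, ~29.8 Hz imaging, 30 fps video
  (the head-fixed video rate is unstated; 30 fps is typical hardware).
  Trial order is drawn by rejection sampling under the protocol
  constraints: first three trials reward, no run of three punishment
  trials (catch trials counted as punishment for the run check, the
  conservative reading), catch trials only in the final 15% of the
  sequence, and punishment trials balanced across the two half-session
  blocks.
* **Licks.** Bernoulli-per-frame at the phenotype's anticipatory rate in
  [CS, US) of reward-type trials and consummatory rate in [US, CS offset
  + 3 s] of rewarded trials, zero elsewhere. Rates are free parameters
  (the source reports none); defaults of 2.5/6 Hz (1.2/4 Hz for
  susceptible mice) give high but non-saturated lick probabilities and a
  positive preference–licking correlation after stress.
* **Neural activity.** Each neuron draws rectified-Gaussian response
  amplitudes to four event kinds (reward/punish CS/US); impulses at event
  frames (scaled by the phenotype-by-epoch valence gain and a lognormal
  per-trial factor shared across neurons) are convolved with a causal
  single-exponential kernel, tau = 0.7 s (GCaMP7f-like; the forward model
  is a package choice, any smooth causal kernel would serve), plus
  Gaussian noise of sd 1 z-unit. Cell identity persists across sessions;
  a configurable fraction (default 0.7) is reported as ROI-matched
  between any session pair.
* **Facial keypoints.** A fixed rest pose plus a two-latent event-locked
  displacement (reward and punishment latents, 0.3-s kernel) mapped
  linearly to the 13 keypoints per mouse, scaled by the phenotype-by-epoch
  facial amplitude, plus Gaussian jitter (default 2 px) and sporadic
  low-confidence dropouts.
* **Planted effects.** Controls ramp their reward gain from 1.0 to 1.5
  across the stress weeks (reward processing strengthens over time);
  stressed groups stay flat through stress and rise only after ketamine;
  susceptible mice carry an elevated reward gain (1.3) already at
  baseline, encoding the finding that susceptibility is decodable before
  stress. Susceptible sucrose preference declines to ~55% at the
  post-stress time point and recovers after ketamine. Facial amplitudes
  are low at baseline and high post-stress for susceptible mice, and
  reduced after ketamine for resilient mice. All of these are
  `PhenotypeSpec` fields, chosen once and documented here; none is claimed
  to match the animals quantitatively.

Cohorts materialize per-session data lazily: `generateCohort()` stores
behavioral scores, ground-truth labels and one derived seed per (mouse,
epoch), and `cohortSession()` regenerates any session byte-identically on
demand. Each session component (trials, licks, neural, keypoints) draws
from its own derived stream, so skipping one component never changes
another's realization. A full default cohort (22 mice x 10 epochs of
~27-minute sessions) would occupy tens of gigabytes as a single eager
bundle; laziness keeps the contract — one session per mouse per epoch —
without that cost.

What the generator does *not* emulate: raw movies or video pixels, motion
artifacts, neuropil contamination, spike-to-fluorescence nonlinearity,
electrode-free behavioral idiosyncrasies (grooming, whisking unrelated to
trials), learning within or across sessions, or ketamine pharmacokinetics.
Passing tests therefore demonstrate that the analysis recovers effects of
the planted kind at realistic noise levels — not that it would be robust
to every artifact of real recordings.

# Numerical choices and degenerate inputs

* Baseline standard deviations below 1e-9 are floored and flagged rather
  than propagating infinities; constant traces z-score to zero.
* Binning is epsilon-guarded so frames lying exactly on a bin boundary are
  assigned consistently regardless of floating-point rounding.
* k-means ties and empty clusters are handled by seeded restarts; the
  curve used for elbow selection additionally takes a warm start split
  from the k−1 solution, which guarantees a monotone WCSS curve. When k
  equals the number of distinct scores the exact zero-dispersion solution
  is returned directly.
* Trials whose peri-event window leaves the recording, and reward trials
  with no lick for first-lick alignment, are dropped and counted, never
  silently imputed.
* Undefined quantities (preference with no licks, correlation with zero
  variance, ratio with zero punishment length, social index with no
  interaction frames, decoding with one class) raise errors naming the
  problem.
* Serialization uses delimited text with YAML sidecars for scalar
  attributes; numeric round-trips are exact to ~15 significant digits.

# Problem sizes used by the test suite

The planted-effect checks run at the smallest cohort sizes that preserve
the study's structure, chosen as a package design decision: 3 mice per
group with 40–80 neurons per mouse and full 48-trial sessions for the
ratio-recovery and baseline-decoding checks (20 seeded cohorts each);
14-trial sessions with short ITIs for the end-to-end pipeline and
jitter-robustness checks. The acceptance script's cluster-count target
uses the full stated condition (three groups at 55/75/90 ± 4, n = 24, 100
seeds).

# Known limitations

* The elbow rule, the facial feature registry, the lick-rate and
  neural-amplitude scales, the SG polynomial order, the confidence
  threshold, and the causal-smoother sd are all package choices where the
  source is silent; each is configurable and documented above.
* Neutral mice are generated on request and exposed by the phenotyper, but
  the trajectory and decoding stages follow the source figures in using
  control/resilient/susceptible only.
* Per-trial decoding samples within a session are not independent of the
  animal's identity; with few mice per group, part of the decodable signal
  is mouse identity. The planted-effect checks compare AUCs between
  comparisons built on the same animals, which cancels that component in
  expectation.
* File-based inputs accept the generator's text formats; HDF5 pose-track
  containers are out of scope for this implementation and would be read
  upstream.
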