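---
title: "Classifying ataxic gait from motion-capture trajectories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying ataxic gait from motion-capture trajectories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ataxgait)
```

## The problem

Cerebellar ataxia disturbs the coordination of walking: affected patients
show increased lateral sway of the trunk, irregular step lengths, reduced
cadence and high-frequency involuntary movement superimposed on the gait
cycle. Wearable motion-capture systems record these effects as
three-dimensional joint trajectories, but a raw recording is far too
high-dimensional for direct clinical use. `ataxgait` implements the classic
shallow-learning route from such recordings to a binary (ataxic vs healthy)
decision: event detection, a small set of interpretable gait features,
feature scaling and class balancing, two-dimensional embedding, and a grid
of standard classifiers evaluated under subject-aware cross-validation.

Because clinical motion-capture recordings are rarely shareable, the package
ships a first-class synthetic gait generator with exact ground truth. Every
stage of the pipeline is tested against quantities that the generator knows
analytically — contact times, per-step lengths, turn intervals — rather than
against another implementation of the same heuristics.

## The synthetic gait model

`generate_recording()` simulates a walk along a corridor as alternating
single-foot swings:

* The swinging foot advances with a cycloid horizontal profile,
  $s(\tau) = L\,(\tau - \sin(2\pi\tau)/2\pi)$, so its velocity vanishes
  smoothly at lift-off and landing; vertical lift is
  $h\,(1-\cos 2\pi\tau)/2$. A landing therefore has a well-defined instant
  at which the foot becomes stationary — the ground-truth stance onset.
* Each step's landing point is placed at a drawn 3-D distance
  $d_k \sim \mathcal N(\mu_{SL}, \sigma_{SL}^2)$ (truncated at the lateral
  foot separation) from the stance foot's contact. The drawn $d_k$ *is* the
  distance between adjacent contacts, so the step-length feature has an
  exact oracle.
* The pelvis — the centre-of-mass proxy — is the stride-window moving
  average of the feet midpoint, plus a lateral sinusoid of amplitude
  $a_{sway}$ at step frequency, plus a tremor component: white noise
  band-limited (FFT brick wall) to a configurable high-frequency band,
  scaled to a target RMS.
* Turns between straight passes are modelled as two quick repositioning
  swings inside a fixed-length turn window; the pelvis heading consequently
  sweeps 180° over roughly the window length. An in-place pivot without any
  foot travel would leave the pelvis velocity — and hence its heading —
  undefined, which is why the turn has a small spatial footprint (the feet
  travel about a metre; the next pass continues on a parallel lane 0.6 m
  over).

Severity enters through `apply_severity()`: a non-negative scalar multiplies
sway amplitude, step-length variability and tremor amplitude upward and
cadence downward ([`effect_sizes()`], defaults sway 1.5, step-sd 1.5, tremor
2.0, cadence 0.15 per unit severity). These couplings are monotone by
construction. The swing path's lateral deviation is tied to the sway
amplitude (gain 1.5), so a severe gait also takes less straight swings and
its step-optimality ratio SL/ST drops — without that coupling the ratio
would be blind to severity, which contradicts how the ratio is meant to
behave clinically.

`generate_cohort()` adds two more layers:

* ataxic severities are drawn uniformly from a configurable range
  (default 0.25–1), healthy participants sit at severity 0;
* every participant receives log-normal multiplicative jitter on their base
  parameters (`subject_cv`, defaults: cadence 2.5%, step length 4%, step
  height 8%, sway 12%, step-length sd 15%, tremor 15%). Without
  between-subject heterogeneity all healthy recordings would be
  statistically identical and even a minute severity shift would be
  trivially detectable; the jitter gives the cohort the within-group spread
  one sees in small adult samples and makes leave-one-subject-out
  cross-validation a meaningful protocol rather than a formality.

Defaults describe the study conditions the package targets: 43 participants
(20 healthy, 23 ataxic), 100 m walks split into two 50 m passes at 60 Hz,
cadence 110 steps/min, 0.65 m steps. With segments capped at 16 contacts
this yields ≈430 straight-gait segments, matching the scale of a few hundred
segments that motivated the design.

What the generator does **not** emulate: upper-body and arm compensation,
stance/swing asymmetries, double-support timing, fatigue drift within a
recording, sensor-fusion artefacts of real IMU suits, and non-stationary
severity. Passing tests on synthetic cohorts therefore demonstrate that the
pipeline recovers structure *of the kinds modelled*; they are not clinical
validation.

## Preprocessing

Recordings at 120 Hz are anti-alias filtered (zero-phase 4th-order
Butterworth, 29 Hz cutoff) and decimated to 60 Hz; naive take-every-other
subsampling would fold energy above 30 Hz into the 15–29 Hz band the
features rely on. All filtering is zero-phase (forward–backward with
odd-reflection padding) so event times are not shifted.

**Foot contacts.** A sample is "grounded" when the smoothed foot height is
below `minimum + 0.1 × vertical range` and the foot speed is below
0.05 m/s; the first sample of each grounded run is a stance onset. Speed is
computed by a ±2-sample central difference: with 2 mm position noise, a
single-sample difference at 60 Hz has ≈0.17 m/s noise — more than three
times the threshold — while the longer baseline brings it down to ≈0.03 m/s.
The grounded mask is then de-flickered morphologically (gaps < 0.15 s
closed, runs < 0.12 s dropped); both constants sit well below physiological
swing and stance durations. On noise-free synthetic walks every ground-truth
onset is recovered within ±2 samples with no spurious detections; with 2 mm
Gaussian noise ≥95% of onsets are matched within ±3 samples.

**Turns.** The pelvis horizontal track is low-pass filtered at 0.5 Hz, the
heading taken as the angle of its velocity, and samples with
|dheading/dt| > 45°/s (dilated by 0.5 s and merged) form turn intervals.
The low cutoff is the load-bearing choice: lateral sway modulates the
instantaneous heading at step frequency (1.5–2 Hz) strongly enough to cross
any reasonable rate threshold, while a 180° turn evolves over seconds.
Heading changes at speeds below 0.1 m/s are ignored — the direction of a
near-zero velocity is noise (standing, gait initiation).

**Segments.** The complement of the turn intervals is cut into maximal
stretches; stretches with ≥4 pooled stance onsets are kept and, at pipeline
scale, split into sub-segments of at most 16 onsets. Four contacts give at
least three steps, the minimum for a meaningful median; the 16-contact cap
is the package's choice for producing a few hundred segments per cohort and
is configuration-exposed, since segment granularity is otherwise
underdetermined.

## Features

Per segment, seven numbers:

| feature | definition | units |
|---|---|---|
| `cadence` | (pooled contacts − 1) / elapsed time | steps/min |
| `step_length` (SL) | median 3-D distance between adjacent contacts | m |
| `step_trajectory` (ST) | median arc length of the swinging foot's path between adjacent contacts | m |
| `relative_step_length` | SL / ST | — |
| `com_std` | SD of the pelvis horizontal coordinate orthogonal to the first principal axis of travel | m |
| `energy_low` | pelvis acceleration periodogram energy, (3, 15] Hz | (m/s²)² per sample |
| `energy_high` | same, (15, 29] Hz | (m/s²)² per sample |

Notes on the choices the definitions leave open:

* *Intervals, not counts*: cadence uses (count − 1)/duration, which is
  unbiased on short segments.
* *Pooled contacts*: step distances pair adjacent contacts regardless of
  laterality, and pairs with zero time gap (simultaneous double-stance
  onsets at a segment boundary) are skipped.
* *SL/ST is bounded by geometry*, chord ≤ arc, and the implementation
  errors on violations beyond 1e-9 instead of clipping — a violation means
  the inputs are inconsistent, not that the value needs repair. In this
  kinematic model the swinging foot travels roughly a stride (two step
  lengths) per swing, so healthy ratios sit near 0.5 rather than near 1;
  only relative comparisons across groups are meaningful.
* *COM sway is lateral-only*: the pelvis horizontal track is rotated so
  forward progress occupies the first principal axis; the SD of the
  orthogonal coordinate is reported. For a lateral sinusoid of amplitude
  $a$ this is $a/\sqrt 2$, which the tests assert to 2%.
* *Acceleration is synthesised from position* by second-order central
  differences, because the pipeline's data model is positional; any joint
  can be substituted. Periodograms use mean removal and a Hann window to
  keep the dominant step harmonic from leaking into the high band. Band
  edges are half-open `(lo, hi]`, so the default bands partition their bins
  and their energies can never exceed the total.

## Scaling, balancing, embedding, classification

Three scalers (min-max, mean normalisation, z-score with population SD) all
retain their per-feature parameters so held-out rows are transformed with
training-fold statistics. Four balancers (majority subsampling, minority
duplication, noise-jittered duplication, SMOTE) equalise class counts on
training folds only and flag synthetic rows; SMOTE interpolates
$x + u\,(x_{nn} - x)$, $u \sim U(0,1)$, among the $k=5$ nearest minority
neighbours in (scaled) feature space.

Embeddings are two-dimensional: PCA (centred, not scaled), t-SNE (exact,
perplexity 30, deterministic PCA initialisation) and UMAP (15 neighbours,
min_dist 0.1, spectral-free `spca` initialisation, fixed seed, single
thread). Ten classifiers form the grid: logistic regression, linear /
polynomial (degree 3) / RBF SVM, naive Bayes, k-NN (k = 5), decision tree,
random forest (100 trees), a single-hidden-layer neural network (100 units,
decay 0.01), and AdaBoost (50 depth-1 stumps, SAMME weighting, implemented
in-package). A quadratic discriminant classifier is registered but not part
of the default grid. All hyperparameters are configuration values recorded
in every run's provenance.

**Leakage regimes.** t-SNE has no parametric out-of-sample map, and it is
common — if optimistic — to embed all segments jointly before splitting.
`evaluate_grid()` therefore offers two modes. *Paper mode* (default) embeds
everything first and balances training folds in embedding space; the
result carries a mandatory leakage warning in its provenance and printed
summary. *Strict mode* fits scaling, balancing and the reducer on training
rows only; t-SNE test points are then placed at the inverse-distance
weighted average of their five nearest training points' embedding
coordinates, and UMAP/PCA use their native transforms. The package treats
paper mode as the replication target and strict mode as the honest
protocol; both are first-class and tested.

**Cross-validation.** A stratified 60/40 holdout and leave-one-group-out
with participant as the group (43 folds at study scale). Metrics are
pooled over test predictions, not averaged per fold — LOGO folds have very
unequal sizes and macro-averaging would overweight short recordings.
Sensitivity is recall on the ataxic class, specificity on the healthy
class.

## Severity separation

Beyond the binary label, a useful embedding should order segments by
clinical severity. `severity_report()` quantifies this with (a) the
Spearman correlation between severity and the projection of the embedding
onto its least-squares severity direction, and (b) the ratio of mean
between-tertile to mean within-tertile pairwise distance. On the default
synthetic cohort the t-SNE embedding reaches rank correlations above 0.9,
and shuffling severities collapses the correlation below 0.1 — the
statistic measures structure, not its own fitting procedure. Both
segment-level and subject-averaged groupings are supported, since the
appropriate unit of analysis is genuinely ambiguous.

## Determinism and numerical choices

Every stochastic stage takes a seed; child seeds are derived by a fixed
multiplicative hash so no two stages share a stream. Embeddings use
deterministic initialisations, single-threaded execution and, for the
k-NN tie-breaks of the knn classifier, a locally seeded RNG. Two pipeline
runs with the same configuration produce byte-identical CSV bundles; each
output file is stamped with the MD5 hash of the canonical JSON
serialisation of the configuration (excluding the output directory, which
must not influence results).

Degenerate inputs are handled by explicit convention rather than silently:
zero-range features scale to all zeros with a warning; single-class
training data yields a constant classifier; a standing recording raises
"no gait detected"; an empty evaluation grid refuses to render any file.

## Problem sizes

The shipped tests and the acceptance script run the full study-scale
configuration — 43 participants, 100 m two-pass walks, ≈430 segments, the
30-cell grid under both cross-validation schemes — in well under an hour on
a single CPU; unit tests use shorter single-pass walks (25–60 m) chosen so
each check still exercises several strides per segment.

## Known limitations

* The generator's gait is sagittally symmetric and stationary; features
  capturing asymmetry or drift would find nothing to detect in it.
* Healthy and ataxic synthetic cohorts differ exactly along the modelled
  couplings, so classification accuracies on synthetic cohorts say nothing
  about accuracies on patients; only the *relative* behaviour of methods
  (e.g. that label permutation drops the grid to chance, or that weaker
  effects reduce accuracy) transfers.
* Paper-mode results are optimistic by construction; strict mode is the
  protocol to quote.
* BVH support covers position-channel and standard Euler-rotation
  hierarchies reduced to world-space joint positions; exotic channel
  orders or scale channels are out of scope.
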