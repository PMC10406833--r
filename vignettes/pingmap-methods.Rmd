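---
title: "Models and methods behind pingmap"
author: "pingmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pingmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Spatial attention is commonly modelled as a priority map: a topographic
representation of visual space in which goal-driven, salience-driven and
history-driven signals compete, and the location with the highest weight
wins selection. The history-driven layer — installed by statistical
learning of where targets tend to appear — is thought to be *activity
silent*: carried by changed synaptic weights rather than ongoing firing,
and therefore invisible to ERPs or oscillatory measures. A task-irrelevant,
high-contrast visual impulse (a "ping") presented between search trials
perturbs the network; if learned priority has primed location-tuned
populations, the evoked response carries a decodable spatial signature.

`pingmap` implements the full analysis chain for such experiments —
experiment-schedule construction, behavioral cleaning and contrasts, EEG
preprocessing and artifact repair, gaze analytics, time-resolved multiclass
decoding with its control variants, and cluster-based permutation
statistics — together with a synthetic-data generator that reproduces the
statistical structure every downstream stage assumes. Every stage is
therefore exercisable, and falsifiable, without any data download.

# The experiment design and its generator

`designConfig()` encodes the search task: 19 experiment blocks of 56
trials (plus a flagged practice block). Blocks come in sequences of four
*biased* blocks, in which one high-probability (HP) location holds the
shape-singleton target on exactly 37.5% of trials (21 of 56; each of the
seven other locations gets 5, a 4.2 : 1 ratio), separated by *neutral*
blocks with a uniform target distribution that serve to extinguish the
learned bias. The HP location cycles over the four cardinal positions
(locations are indexed 0–7 with 0 = right, counting counter-clockwise; the
cardinals are 0/2/4/6). Exactly half the trials carry a ping. Colour
singleton distractors appear on 40 trials per block, exactly 5 at each
location and never at the target's location; 40 is the only
location-balanced count near the nominal 70% distractor rate
(0.7 × 56 = 39.2 is not an integer). Within a block only the *order* of
trials is random; all counts are exact.

A consequence of exact-count randomisation worth recording: the expected
number of immediate target-location repeats in a random permutation of a
multiset with class counts $c_i$ is $\sum_i c_i(c_i-1)/n$, i.e. 10 per
biased block (17.9% of trials) and 6 per neutral block. The repeat-trial
exclusion that controls the HP contrast for intertrial priming therefore
removes ≈18% of biased-block trials. Repeats are defined within a block
only; block breaks reset the comparison.

Reaction times are generated as
$$\mathrm{RT} = \mathrm{baseline} - b_\mathrm{HP}\,[\text{target at HP}]
  - b_\mathrm{rep}\,[\text{repeat}] + c_\mathrm{D}\,[\text{distractor}]
  + c_\mathrm{DHP}\,[\text{distractor at HP}] + \varepsilon,$$
with ex-Gaussian noise $\varepsilon$ (Gaussian σ = 60 ms plus an
exponential tail τ = 100 ms, the standard RT shape — it is what makes the
2.5 SD trim meaningful) and a Bernoulli error rate of 11%. Defaults
(baseline 650 ms, HP benefit 45 ms, repetition benefit 55 ms, distractor
cost 25 ms, extra cost at HP 26 ms) are in the tens-of-milliseconds range
typical of this paradigm. Note one deliberate realism: because repeats
concentrate at the HP location, the *raw* repeat-vs-switch contrast
overestimates the repetition benefit — exactly the confound structure the
analysis variants exist to separate.

## The EEG signal model

`signalModel()` composes each epoch (64 scalp channels, two earlobe
references, VEOG/HEOG; 512 Hz; −700…1100 ms around the ping trigger) from:

* **Background noise** — a spatially mixed 1/f component (random channel
  covariance; no head model, but still topographic) plus
  channel-independent broadband sensor noise (30% of variance by default).
  The split matters: brain background is spatially correlated, amplifier
  noise is not, and the EMG detector's channel-summed z statistic behaves
  very differently under the two. Total per-channel SD 10 µV.
* **A class-independent ping ERP** (12 µV, Gaussian kernel peaking at
  150 ms) on ping trials only.
* **The class-specific pattern** — one fixed unit-norm random channel
  vector per HP location, 8 µV at peak, with a Gaussian temporal kernel
  peaking at 350 ms with width 50 ms so that the injected information spans
  the 300–400 ms window. Present *only* on ping trials of biased blocks:
  this is the generator's statement of the activity-silent hypothesis, and
  with this gain set to zero the epochs are exchangeable across HP labels.
* Optionally: a pattern keyed to the *previous* trial's target location
  (8 classes, weak by default — the intertrial-priming trace), a slow
  linear drift of the evoked response across the experiment (the temporal
  confound that dummy decoding must catch), band-limited 110–140 Hz EMG
  bursts on 1–3 channels of a logged fraction of trials, and blinks on
  VEOG plus frontal channels, also logged.

A common sinusoidal "recording reference" signal (15 µV) is added to every
channel including the earlobes, so that earlobe re-referencing does real
work. Evoked amplitudes of a few µV against ~10 µV background are the
typical evoked/background ratio for scalp EEG.

Electrode positions are computed, not shipped: an idealized spherical
10-10 construction places the midline and the 10% circumferential ring at
multiples of 18° from the vertex and interpolates interior electrodes
along great circles. The montage is exact-sphere and anatomically
idealized — adequate for spherical-spline interpolation and simulation,
not for source analysis.

## Gaze

`generateGaze()` emits native tracker coordinates (top-left origin,
y down) at 500/1000/2000 Hz: a mean-reverting fixational walk (stationary
SD 4 px), an optional constant offset toward the current HP location, an
optional slow drift, logged blink windows filled with off-screen samples,
and an optional fraction of trials with a sustained large deviation (for
the gaze-exclusion stage; 58 px ≈ 1.5° at the default geometry of 38.5
px/°, i.e. a 1920-px, 52.7-cm monitor at 60 cm).

# Preprocessing

`preprocessRaw()` re-references to the earlobe average, high-passes at
0.01 Hz with a zero-phase Hamming-window FIR, and epochs around the ping
triggers. A literal 0.01 Hz transition band implies a ~340 s filter at
512 Hz, longer than the recordings the package simulates, so the filter
length is capped at a third of the recording; `highpassGain()` exposes the
*designed* response of the filter actually used, and the tests verify
measured attenuation against it rather than against an unattainable ideal.

`emgScanRepair()` detects muscle artifacts: band-pass 110–140 Hz,
analytic-signal envelope smoothed 200 ms, z-scored per channel across
trials, channel-summed; the per-trial statistic is the maximum of that sum
within the −200…600 ms inspection window. Two choices are deliberately
robust where the underlying toolkit leaves them open: the z-scoring uses
median/MAD (so artifact trials cannot mask themselves by inflating the
scale) and the subject-adaptive threshold is median + 3 MAD of the
per-trial statistic (configurable; a fixed threshold can be supplied
instead). Marked epochs get their five top-contributing electrodes
spherically spline-interpolated one at a time, re-testing after each —
interpolation never increases the statistic — and are dropped only if the
threshold is still exceeded. Everything is logged.

Spherical-spline interpolation follows the classic order-4 formulation
(Legendre expansion truncated at 50 terms, ridge 10⁻⁵, mean-constraint
row). It reproduces low-order spherical-harmonic fields to well under 1%,
is exact on constants, and is linear in the data; more than 25% bad scalp
channels is refused.

`excludeByGaze()` baselines gaze on the 300 ms pre-ping window, averages
40 ms segments, and drops trials whose maximum Euclidean segment deviation
exceeds 1° (Euclidean, not per-axis — the less forgiving reading). If more
than 30% of a subject's trials would drop *and* the gaze stream is flagged
low quality, the subject falls back to an HEOG step detector (200 ms
window, 10 ms step, 20 µV threshold).

# Decoding

`decodeTimecourse()` implements the time-resolved pipeline: baseline
(−200…0 ms) then block-average downsampling to 128 Hz (in that order),
pseudo-trial averaging over `avg_k` same-class trials (3 by default; 5 for
the 8-class previous-target variant; 1 where counts forbid averaging),
ten stratified folds, and per fold and timepoint a PCA fitted on the
training fold only (components explaining 99% of training variance),
projection of both sets, LDA, and macro-averaged one-vs-rest AUC on the
held-out fold. AUC is criterion-free and has chance 0.5 for any class
count. Multiclass AUC is macro OvR on the LDA posteriors (the common
choice; it reduces to ordinary AUC for two classes). The AUC itself is a
rank (Mann–Whitney) statistic; an independent ROC implementation serves as
a cross-check in the tests, not as the engine.

Two structural choices deserve a note. Pseudo-trials are formed *before*
fold assignment, mirroring the described pipeline order; under the null
this is leak-free (no trial appears in two folds), but with signal it is a
mild optimism source relative to per-fold averaging. Fold assignment keeps
*exactly* equal class counts in every fold: each class contributes
`floor(min class count / n_folds)` pseudo-trials per fold, resolving class
imbalance by seeded subsampling to the minimum class count (with a
warning). The cost is real — 18 pseudo-trials per class are truncated to
10 under a 10-fold scheme — which is why the recovery checks run on the
full 19-block design (30 usable per class) rather than a reduced one.

`runVariant()` encodes the analysis variants: `hp_ping` / `hp_noping`
(4 HP classes, biased blocks, ping or matched no-ping trials), `dummy`
(three temporal phases, each spanning the last biased block of an HP
sequence, its neutral block, and the first two biased blocks of the next
sequence — 224 trials per phase, deliberately tilted toward the *next*
regularity to avoid lingering-bias overlap), `prev_target` (8 classes,
all blocks including neutral), `hp_exclusion` (drop trials whose previous
target was at the current HP — ≈37.5% of biased-block trials),
`hp_only` (only those trials, no averaging), and `gaze_features` (the two
gaze coordinates as features).

# Statistics

`clusterPermTime()` and `clusterPerm2d()` implement cluster-based sign-flip
permutation tests: per-point t against the reference, two-sided
cluster-forming threshold at p < 0.05, cluster mass = sum of t over a
contiguous run (1-D) or 4-connected component (2-D), and a max-|mass| null
from 1024 random sign flips of the subject-level differences. One
implementation subtlety is load-bearing: the per-permutation t must use
the *sign-flipped* sample SD. The mean square is flip-invariant, so
$s_p^2 = (\overline{d^2} - \bar d_p^2)\,n/(n-1)$ is computed from the
flipped mean alone; reusing the observed SD inflates the family-wise error
severely (we measured ~40% instead of 5%). Because the identity and
all-negated assignments reproduce the observed mass, the attainable
p-value floor is about $3/(n_\mathrm{perm}+1)$, not
$1/(n_\mathrm{perm}+1)$. Any display smoothing of AUC curves is exactly
that — display; statistics always run on raw curves.

Behavioral statistics follow the cleaning cascade in order (accuracy-based
subject exclusion → correct trials → per-subject 2.5 SD RT trim →
group-level RT subject exclusion), paired two-sided t-tests with
$d_z = t/\sqrt n$, and a 2 × 4 repeated-measures ANOVA (target location ×
experiment phase) via `aov()` with an `Error(subject/(loc*phase))` term;
generalized eta squared is computed from the effect and subject-related
error sums of squares.

# What the generator emulates — and what it does not

Passing tests on synthetic data show that the *pipeline* is correct: exact
design counts, label exchangeability at chance, recovery of injected
effects, detection of an injected temporal confound by the dummy control,
nominal type-I error of the permutation machinery, and artifact detection
against ground truth. They do not show that real EEG contains a
ping-evoked priority signal. Real data differ in ways the generator does
not attempt: volume-conducted topographies from actual sources,
non-Gaussian and non-stationary noise, oscillatory structure (alpha in
particular), saccade dynamics beyond a drift-plus-jitter walk,
and between-subject variability in SNR and geometry. The generator's
class patterns are random unit vectors — topographic but anatomically
arbitrary.

# Problem sizes and numerical choices

The test-suite and acceptance-script simulations use 6 simulated subjects
for group-level cluster statistics (the minimum the permutation test
accepts), full 19-block schedules where the variant needs the complete
block structure (dummy phases, previous-target counts) restricted to the
trials the variant consumes, epochs over −250…650 ms (the decode window
plus margin), and 22 replicate schedules for design-count statistics.
These sizes were chosen so each property has clear power at desk scale;
they are configuration, not limits of the method. Noise generation uses a
composite FFT length (padding from `nextn`) for the 1/f component;
decimation to 128 Hz is by block averaging; ex-Gaussian and Poisson event
counts come from R's RNG under a single master seed per run, with child
seeds derived arithmetically so every stage is reproducible in isolation.
Assertions on a "no significant cluster" outcome carry an irreducible 5%
family-wise false-positive rate by construction; fixed seeds make them
deterministic.

Known limitations: no ICA (blink handling is regression/selection based;
blinks are generated and logged but their removal is out of scope), no
BDF/EDF or HDF5 I/O (epoch containers persist as RDS plus plain-text trial
tables, events, and ASC-like gaze logs), no source analysis, no temporal
generalization or searchlight decoding, and no Bayesian statistics.
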