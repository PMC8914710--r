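---
title: "Single-sensor sEMG motion-intent recognition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-sensor sEMG motion-intent recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgintent)
```

## The problem

A surface-EMG (sEMG) electrode over one muscle records that muscle's
activity plus attenuated contributions from its neighbours (crosstalk).
`emgintent` classifies motion intent from such a *single* channel: the
signal is conditioned, its power spectral density (PSD) is estimated over a
short sliding window, four frequency-domain features summarise each window,
and one of two white-box classifiers maps feature vectors to action labels.
Performance is scored at the level of ground-truth *action windows*, the
unit a neuroprosthesis controller would act on.

The package targets two acquisition settings: an able-bodied protocol (a
trapezius-descendens sensor at 10 kHz; shoulder raise SR, shoulder forward
SF, shoulder backward SB, plus raise-and-hold SRH and object raise OR used
only as "unknown" actions) and a tetraplegic protocol (a platysma sensor at
2.15 kHz; platysma contraction PC and shoulder raise SR seen through
crosstalk).

## Signal conditioning

Raw sEMG is band-pass filtered with a 4th-order Butterworth (corners 20 and
500 Hz). The default is single-pass causal filtering, because the intended
use is an online human–machine interface; a zero-phase forward–backward
option exists for offline analysis. Start-up transients of the causal pass
are suppressed by conceptually starting the filter from the steady state of
a step at the first sample (implemented by constant padding, which converges
to that steady state).

An envelope channel — full-wave rectification followed by a 2 Hz 4th-order
Butterworth low-pass — is provided for visualisation; the classifiers never
see it. For 10 kHz recordings the conditioned signal is decimated by 4 with
an 80th-order linear-phase FIR (cutoff at the new Nyquist, group delay
compensated), giving a 2.5 kHz analysis rate.

## Spectral features

Every 10 ms (the analysis stride), the trailing 0.2 s of signal is analysed
with Welch's method: 0.05 s Hann-tapered, mean-detrended segments with 50%
overlap, averaged into a one-sided PSD in µV²/Hz. Segments are zero-padded
so the PSD bin spacing does not exceed 8 Hz. Four features summarise each
window over the 20–500 Hz band:

* **band power** (µV²) — trapezoidal integral of the PSD;
* **PSD peak** (µV²/Hz) — the largest PSD value in the band;
* **mean frequency, MNF** (Hz) — the power-weighted spectral centroid;
* **median frequency, MDF** (Hz) — the half-power frequency, interpolated
  linearly inside the crossing bin with each bin's power spread uniformly
  over its width (so a point-mass PSD returns that bin's frequency exactly).

Because "mean and median of the PSD" can also be read as statistics of the
PSD *amplitudes*, `welch_spec(feature_variant = "amplitude")` switches to
that reading; all defaults use the standard frequency descriptors.

Windows with zero band power yield an all-zero, flagged feature vector and
are never classified as an action.

**Numerical choices.** The FFT length is the smallest 5-smooth integer at
least `fs / 8`: a 5-smooth length keeps the mixed-radix FFT fast while the
bin spacing stays at or below the 8 Hz target (7.81 Hz at 2.5 kHz, 7.96 Hz
at 2.15 kHz). Band integration is trapezoidal with interpolated band edges.

## Classifiers

### CART decision tree

Greedy binary partitioning on the four features with the Gini impurity
`G = 1 - sum(p_c^2)`; candidate thresholds are midpoints between consecutive
distinct sorted values, ties broken toward the lowest feature index and
smallest threshold; samples equal to a threshold go left. Balanced class
weights `N / (n_classes * N_c)` stop the abundant no-action class from
dominating. Pre-pruning (maximum depth, minimum leaf size, minimum split
size) is selected by grid search — depth {2, 3, 4, 6, 8, 10} × leaf size
{5, 20, 50, 100}, split size tied to twice the leaf size — scored by
window-level cross-validated accuracy, with ties resolved toward the
simplest model (smaller depth, then larger leaves). When unknown-action
windows accompany a task, the grid is scored on the pooled accuracy so the
chosen pruning is also robust to actions absent from training.

Training labels deserve care. Scoring uses action windows twice the nominal
movement duration (below), but teaching the tree that *every* vector in such
a window is the action would make roughly half of each action class
rest-like; with balanced weights the tree then plants action leaves inside
the rest cloud and window accuracy collapses. Training labels therefore come
from annotated movement intervals (in practice audiovisual annotation; in
simulation the generator's ground truth) under a conservative containment
rule: a vector is an action example only if its whole 0.2 s analysis window
lies inside the movement. Vectors straddling movement boundaries — whose
spectra mix movement and rest — count as no-action. When no movement
annotation is available, `crossvalidate()` falls back to labelling by
action-window midpoint.

### Median / third-quartile thresholding

For each occurrence of an action, the maximum of each feature over the
occurrence's action window is extracted; per class and feature, the median
of these maxima is the lower decision bound, and (for multi-class problems)
the third quartile — linear-interpolation quantile — caps the class from
above. Classes are ordered by ascending median band power. A vector is
assigned the highest class whose lower bounds it satisfies on **all four**
features; a non-top class additionally requires the vector at or below its
upper bounds, otherwise the vector falls through to no-action. The
between-band fall-through is deliberately conservative: for neuroprosthesis
triggering, an ambiguous vector should not fire an action. "Satisfied" means
*at or above* the bound: in the regimes simulated here contractions raise
all four features above rest, because the resting signal is dominated by
low-frequency baseline activity.

A structural property worth knowing: for continuous, exchangeable
per-occurrence maxima, the probability that a held-out occurrence exceeds
the training median is at most one half, per feature. The thresholding
classifier therefore detects at most about half of held-out action
occurrences, and its high window-level accuracies arise because no-action
windows dominate the timeline. This ceiling is intrinsic to the median rule,
not to the implementation.

## Ground truth and scoring

Each instruction event defines an action window `[t, t + 2 * duration)` —
twice the nominal movement duration, starting at the instruction. The rest
of the recording is partitioned into no-action windows whose length matches
the mean action window, so both window types count in comparable units
(slivers shorter than 30% of that length are dropped). A truth-action window
scores as the first *wrong* action predicted anywhere inside it; otherwise
as the correct action if predicted anywhere; otherwise as no-action.
No-action windows score as the first action predicted inside them, or
correct. Accuracy is the confusion-matrix trace over the total.

Cross-validation stratifies *windows* (not raw sliding vectors) into k
folds by per-class shuffled round-robin, so overlapping analysis windows
never straddle the train/test divide — stricter than stratifying raw
vectors, and it removes the optimistic bias that temporal leakage would
introduce. If a class has fewer windows than k, k is reduced to that count
with a warning. Unknown-action occurrences (SRH, OR) can be pooled with
every fold's test windows, ground-truthed as no-action, to probe robustness.

## The synthetic generator

No recordings accompany the method, so `synth_session()` builds sessions
with the statistical structure the method assumes. Its defaults encode the
acquisition protocols:

* **Cycle timing** — relax 2 s, prepare 2 s, instruction, act; 12
  repetitions per action for `protocol_a` (blocked trials, ±30% effort
  variation as instructed in that protocol), 15 per class and day for
  `protocol_b_p2` (interleaved verbal instructions, two days with different
  sensor gains, ±50% effort variation reflecting impaired effort control).
  Protocol B's inter-instruction rest is set so the no-action : action
  window-time ratio is ~11.5 : 1, matching the published per-class sample
  counts for that participant.
* **Background** — a white sensor-noise floor plus a low-frequency (20–40
  Hz) baseline component (motion-artefact residue and distant tonic
  activity). The baseline dominates rest power, so contractions *raise* MNF
  and MDF — the regime the threshold direction assumes.
* **Bursts** — band-limited Gaussian noise per source, mixed by
  per-movement gains (non-target gains model crosstalk), amplitude-modulated
  by an envelope: ballistic `quick` (70 ms ramps), `graded` (slow rise-fall
  of weak voluntary activation), `hold` (isometric plateau) and `object`
  (double bump: lift then lower). Two stylised physiological mechanisms make
  the four features informative: an *effort-coupled spectral shift* (the
  upper half of the source band gains weight as instantaneous effort rises,
  as faster motor units are recruited) and a *synchronised-firing tone* (a
  deterministic tone swept along the instantaneous band centroid, carrying
  50–85% of burst power) that concentrates the PSD the way synchronised
  discharge does in weak or fatigued muscle.
* **SNR calibration** — per action, bursts are scaled so the realised
  action-window SNR (20–500 Hz band power, action windows over rest) hits
  the target within ±1 dB. Published values anchor the targets: SR 6 dB and
  SF 2.5 dB on the trapezius sensor; SB (5 dB), SRH (2.5 dB, lower momentum
  when a hold is anticipated), OR (3 dB), and the platysma-sensor PC (9 dB)
  / SR (5.5 dB) are this package's choices consistent with the reported
  orderings.
* **Spectral ladder** — sources occupy distinct bands (protocol A: SRH/OR
  30–55 Hz, SF 70–130 Hz, SB 130–220 Hz, SR 210–330 Hz; protocol B: SR
  35–150 Hz, PC 70–240 Hz). These are wider and higher than typical surface
  EMG, where most power sits between 20 and 150 Hz; the generator's purpose
  is to encode *that* actions are spectrally distinguishable at the sensor,
  not to reproduce motor-unit physiology. Determinism is per-burst: each
  (action, repetition) has its own substream of the master seed, so editing
  one action leaves the others' waveforms untouched.

**What passing tests do and do not show.** The generator produces stationary
rest, clean class-specific bands and no electrode shift, powerline
interference, movement artefacts or fatigue drift. Success on these presets
demonstrates that the pipeline — conditioning, features, classifiers,
window-level evaluation — is implemented correctly and behaves as designed
under the assumed signal structure; it does not certify performance on real
recordings.

## Problem sizes and runtime choices

The replication drivers run one `protocol_a` session (60 events, ~452 s at
10 kHz, ~45k feature vectors after decimation at a 10 ms stride) and one
two-day `protocol_b_p2` study (30 events and ~750 s per day at 2.15 kHz,
~75k vectors per day). The hyperparameter grid search uses 3-fold
cross-validation and the reported scores fresh 10-fold (protocol A) or
5-fold (protocol B, matching the published analysis) cross-validation; the
acceptance script averages five replicate seeds. These sizes keep a full
replication within minutes on one CPU while leaving every class with enough
occurrences for stratified folds.

## Known limitations

* The thresholding classifier's detection ceiling (≤ ~50% of held-out
  occurrences per class) bounds its window accuracy by the no-action share
  of the timeline; the best-day accuracy reported for the platysma protocol
  sits close to that bound.
* The multi-class band composition rule (highest class first, third-quartile
  caps on lower classes, conservative fall-through) is one consistent
  reading of a rule that is underdetermined in prose; it is isolated in
  `predict_threshold()`.
* Per-participant, per-day models only: no pooling across participants or
  days is implemented, matching the individualised-calibration setting.
* The CLI reads uncompressed CSV/JSON only; live device streaming and
  EDF/BDF are out of scope.
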