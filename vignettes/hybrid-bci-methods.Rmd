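---
title: "Models and methods behind hbci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hbci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbci)
```

`hbci` models a hybrid brain–computer interface in which continuous
wheelchair steering comes from motor-imagery (MI) EEG and discrete
command selection comes from flash-synchronized electrooculography
(EOG). This vignette explains the models, the parameters that matter,
what the synthetic generators do and do not emulate, and the numerical
and design choices that were genuinely open.

## The MI decoding model

Imagined hand movement desynchronizes the mu (8–12 Hz) and beta
(18–26 Hz) rhythms over the contralateral hand area: right-hand imagery
attenuates oscillatory power at C3, left-hand imagery at C4. The decoder
treats this as a two-class spatial-variance problem.

Each band-passed trial `X` (9 channels × N samples, µV) contributes the
trace-normalized covariance `R = X Xᵀ / tr(X Xᵀ)`; normalization makes
trials commensurate regardless of overall amplitude. Per-class sums
`SUM_l`, `SUM_r` enter the generalized eigenproblem of
`(SUM_l, SUM_l + SUM_r)`, solved by whitening the composite and
eigendecomposing the whitened left-class sum. Generalized eigenvalues lie
in [0, 1] and measure the left-class share of variance in each spatial
direction; the `m/2` largest and `m/2` smallest eigenvectors form the
filter `W`, scaled so `W (SUM_l + SUM_r) Wᵀ` has unit diagonal. When the
composite covariance is numerically singular a Tikhonov ridge
(`1e-8 · trace · I`) is added and the event is messaged, never silent.

Features are log variance fractions
`F_k = ln(d_k / Σ_j d_j)`, `d = diag(W R Wᵀ)` — so `exp(F)` always sums
to one and each entry is non-positive, a compact, scale-free summary of
where the band power went. A linear SVM (cost 1 by default) on `F` gives
the decision score `c`. Because the underlying SVM library assigns its
decision sign by class encounter order, training explicitly re-orients
the score so left trials average negative; everything downstream assumes
left-negative/right-positive.

Printed dimensions for the filter and feature in the source literature
are inconsistent with the defining equations; the package implements the
only dimensionally consistent reading (`W ∈ R^{m×M}`, `F ∈ R^m`).

**Tunable parameters.** `m` (spatial components, default 4 — two per
class tail, a conventional choice for 9 channels); band edges (8–30 Hz);
SVM cost; all exposed as arguments.

### Online scoring and steering

The online system evaluates a 2-s epoch every 0.2 s; the score at time
`t` uses the half-open sample window `(t − 2, t]`, so a stream of
duration `T` yields `floor((T − 2)/0.2) + 1` scores. Steering compares
each score to the idle baseline `C_idle` with strict dual thresholds:

* LEFT iff `c < C_idle` and `|c − C_idle| > TH_l`
* RIGHT iff `c > C_idle` and `|c − C_idle| > TH_r`
* otherwise NEUTRAL.

Boundary scores are neutral by the strict inequalities, which is the
safe direction for a wheelchair. The displayed control value is the
instantaneous score; whether a real GUI bar should instead integrate
scores over time is an open presentation question, and an optional
exponential smoothing hook exists but defaults off, because integration
adds latency to STOP-like corrections.

`C_idle` is renewed by averaging scores over a rest window — 3 s by
default, with 10 s as the conservative variant for long sessions (both
appear in practice; the package keeps the choice in config rather than
pretending one is canonical). Thresholds move in ±0.2 steps and clamp at
zero with a warning.

## The EOG selection model

Buttons flash cyclically: 9 buttons × 100 ms on the wheelchair panel,
6 × 150 ms on the arm panel, a 900-ms round either way. Each flash opens
a 600-ms epoch (150 samples at 250 Hz) on the forehead EOG channel.

A blink is present iff (i) the epoch's global peak reaches `amp_min`,
(ii) the maximum absolute first difference reaches `slope_min` (rules
out slow drifts), and (iii) the above-half-peak duration falls in
`dur_range` (rules out both spikes and sustained deflections). A
deflection whose above-half run touches the epoch boundary is rejected
in that epoch — its true duration is unknowable there, and the
overlapping neighbour epochs see it whole; without this rule a sliced
eyebrow raise masquerades as a blink. A detected blink is *intended* iff
its flash-to-peak latency lies in the calibrated delay window and its
peak strictly exceeds `TH_a`.

The delay window is per-user: blink reaction latency varies between
users but is stable within one, so calibration centres a fixed-width
window (default 40 ms) on the median observed latency. A 40-ms window
against a ≥100-ms flash interval guarantees unique attribution of a
blink to a button, which `attribute_blink()` enforces.

Eyebrow raises share the gate family but are discriminated by duration:
their above-half-peak run must exceed the blink duration maximum. The
detector timestamps them by the centre of that run, not the raw maximum
— the maximum of a noisy plateau wanders by tens of milliseconds, the
run centre does not.

**Concrete defaults** (`amp_min` 100 µV, `TH_a` 200 µV, `slope_min`
5 µV/sample, blink duration 100–400 ms, eyebrow > 400 ms, positive
polarity at the forehead) are calibration choices in config, not
physiological constants; the thresholds of the original multi-threshold
check live in prior work and are not public.

### The selection state machine

An intended blink preselects its button (no command); an eyebrow raise
within the verification timeout emits the command and resets; the
timeout elapsing resets silently. Two choices were genuinely open and
are package decisions: the verification timeout (3 s — long enough for
a deliberate eyebrow raise, short enough that a stale preselection
cannot linger) and re-preselection (a second intended blink overwrites
the first, letting the user correct a wrong preselection without
waiting out the timeout). Motion commands are always dispatchable;
parameter commands (threshold ±, renewal, panel switch) require the
wheelchair to be fully stopped and are rejected with a reason otherwise.

## The synthetic generators

`gen_mi_trial()` models ERD as amplitude attenuation: Gaussian broadband
noise (SD 10 µV) on all nine channels, mu + beta sinusoids (10 and
20 Hz, 10 µV, random phases) on C3 and C4, with the contralateral
amplitude scaled by `1 − erd_depth` during imagery. The default
`erd_depth` 0.6 represents a strong but realistic desynchronization.
`gen_training_session()` builds the full cue protocol — 5 s rest, 2 s
fixation cross, 5 s imagery per trial, 40 balanced randomized trials —
with rest-state rhythms at full amplitude.

This generator deliberately omits volume conduction (an optional mixing
matrix can reintroduce channel correlation), 1/f background structure,
eye/muscle artifacts in the EEG, and non-stationarity of the rhythms.
Consequently a passing decoder test shows the pipeline extracts
lateralized variance structure correctly — it does not predict human
online performance, where those nuisances dominate individual
differences.

`gen_eog_stream()` writes intended blinks as raised-cosine bumps
(400 µV, 250 ms) peaking a Gaussian latency (300 ± 5 ms) after the
target's flash, eyebrow raises as smoothed plateaus (350 µV, 550 ms),
and spontaneous blinks as a Poisson process (default 15/min, amplitudes
200 ± 25 µV... truncated at 1 µV) over 15-µV Gaussian background. Real
EOG adds saccades, drift and lid-flutter that this model omits; the
generated streams are best read as a controlled test bed for the timing
and threshold logic. Two residual error modes survive even at high SNR,
exactly as they would in reality: a spontaneous blink colliding with a
scripted one corrupts its peak time, and peak-localization jitter can
push a latency just outside the 40-ms window. Pooled scripted-selection
accuracy at default settings runs ≈96%.

## Plant simulation and numerical choices

The wheelchair is a kinematic unicycle: speeds are commanded, not
dynamic (±0.2 m/s linear, ±0.1π rad/s ≈ 18°/s angular). Integration is
explicit Euler at `dt = 0.02 s` — ten plant steps per decoder step —
updating heading before position. For piecewise-constant inputs the
position error of one step is bounded by `v·ω·dt²/2 ≈ 1.3 × 10⁻⁵ m`,
far below the 0.01–0.1 m scales of interest; the closed-loop
stop-overshoot simulation agrees with the closed-form
`speed × stop_latency` product to within one step (4 mm at 0.2 m/s).
The stop reaction time (~1.15 s in the live system) is an input
parameter here, not a derived quantity: it is an empirical property of
a human-in-the-loop pipeline the simulator does not model.

The grasp workspace box does not come with assigned axes in its source
description; the package reads "length 0.8 m" as the depth extent
beginning at the 0.4-m front face, "width 0.4 m" as lateral (±0.2 m),
"height 0.6 m" as vertical from the box floor.

Degenerate inputs are rejected loudly: all-zero trials, zero projected
component variance, streams shorter than a scoring window (empty result
plus warning), renewal windows the stream cannot cover, event tables
with decreasing onsets, re-referencing an already-referenced montage.

## Statistics

Session significance uses the strict binomial tail
`p = P(X > a)`, `X ~ Bin(num, ½)`, computed exactly (no normal
approximation). The strict convention is kept deliberately: under it a
40-trial session first becomes significant at the Bonferroni level
0.05/9 with `a = 28` correct trials, i.e. a 70% accuracy floor. The
package calls this the *significance floor* rather than "chance level"
— guessing chance is 50%; 70% is where a nine-session family-wise test
clears α = 0.05. Comparing against the unrounded 0.05/9 or the rounded
0.0056 gives the same floor at 40 trials; both levels are accepted.

The misrecognition probability of a spontaneous blink is the
pre-verification false-positive rate divided by the spontaneous blink
rate; at 1.5/min against the normal 10–20 blinks/min this spans
7.5–15%, which the verification stage then suppresses to harmless
preselections.

## Problem sizes used in the tests

The suites run 40-trial sessions (the standard session length), 10-fold
cross-validation, 5–10-minute EOG streams for rate estimates, and
ERD-depth sweeps over {0, 0.3, 0.6, 0.9} averaged over three seeded
replicates — sizes chosen so every statistical check has adequate power
at desk scale while the whole suite stays fast enough to run on every
change.

## Known limitations

* The EEG generator's ERD-on-sinusoids model makes CSP's job easier
  than real volume-conducted, non-stationary EEG does; decoding
  accuracies on synthetic sessions are upper bounds.
* EDF support covers the 16-bit core format (single data record, no
  annotations/EDF+).
* Model serialization is defined for the linear-kernel SVM (hyperplane
  weights travel in the JSON container); non-linear kernels work in
  memory but are refused by the writer.
* Multi-class MI, adaptive CSP retraining, gaze decoding and artifact
  removal are out of scope.
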