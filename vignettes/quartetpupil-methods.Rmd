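---
title: "Pupillometry, musical features, and AR(1) mixed models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pupillometry, musical features, and AR(1) mixed models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quartetpupil)
```

## What the package computes

Task-evoked pupil dilation indexes the intensity of attention — mental
effort. In ensemble performance the demands on a musician fluctuate bar by
bar with the technical difficulty of the part, the harmonic complexity of
the music, and the bodily effort of playing; a listener hearing the same
music faces a related but distinct stream of demands. `quartetpupil`
implements an analysis chain that puts all of these on a common per-bar
timeline and asks, through mixed-effects models, which of them move the
pupil:

1. **Pupil preprocessing** — binocular averaging, blink removal by a
   low-diameter gate, blink-edge removal by a velocity gate,
   Savitzky-Golay smoothing, linear gap interpolation, baseline
   differencing.
2. **Bar timeline** — anchor-interpolated bar onsets; every sample stream
   is aggregated to per-bar values (mean for pupil and sound level, sum for
   motion).
3. **Predictors** — quantity of motion from motion-capture markers, framed
   RMS sound level from audio, spiral-array cloud diameter from spelled
   scores, and per-bar 1–7 ratings of technical difficulty, harmonic
   complexity and expressive difficulty.
4. **Models** — Gaussian linear mixed models by maximum likelihood with
   crossed random intercepts for subject and piece and an AR(1) residual
   process over bar number within each subject-piece series, followed by a
   hierarchical predictor-addition comparison (likelihood-ratio
   chi-squares, BIC), per-performer between-piece contrasts, and a
   Wilcoxon signed-rank comparison of resting baselines.
5. **Synthetic studies** — a seeded generator that produces every raw
   stream with known ground truth, so the entire chain is verifiable
   without access to any recordings.

## The pupil cleaning chain

Eye trackers report left and right pupil diameters in mm at 60 Hz. The two
eyes are averaged (a sample with one missing eye uses the other; both
missing is a gap): averaging damps single-eye outliers at extreme gaze
angles. Blinks appear as diameters collapsing toward zero; a sample more
than 2 SD *below* the trial mean is discarded. The gate is one-sided —
dilation is the signal of interest — and strict at the boundary, a
measure-zero convention fixed for reproducibility.

Blink gaps are flanked by samples where the eye was captured partially
closed. These are caught by a velocity gate: the first difference of
diameter over the first difference of time, formed across retained samples
(gaps are skipped) and assigned to the later sample of each pair; samples
whose velocity deviates from the trial mean velocity by more than 2 SD
(two-sided, strict) are discarded. Velocity statistics are computed *after*
low-outlier removal by default — blink zeros would otherwise dominate the
velocity SD — but `velocity_on_raw = TRUE` reproduces the alternative
order, since the natural-language description of the procedure does not
pin it down. The SD in both gates is the sample estimator.

The retained samples are smoothed with a Savitzky-Golay filter (order 3,
window 11). The filter is implemented from the polynomial least-squares
normal equations; at the series edges the polynomial is refitted on the
truncated asymmetric window, so the output length equals the input length.
Order-3 polynomial inputs are fixed points of the filter to machine
precision, which the tests exploit as an oracle. Gaps are then filled by
linear interpolation against time (leading/trailing gaps take the nearest
retained value — interpolation is only defined for interior gaps), and the
trace is expressed as the difference from the mean diameter of a cleaned
resting baseline recording. Baseline differencing makes traces comparable
across subjects and occasions and is shift-equivariant by construction.

All samples stay on the original sampling grid until bar aggregation; no
resampling is performed.

## Bar timelines

Scores give bar counts; recordings give time. The mapping between them is
anchored at a small set of `(bar, time)` points read off the audio, with
bars assumed evenly spaced within each anchor span and the final span's
rate extrapolated beyond the last anchor. Two anchors (start and end)
reproduce a globally even spacing; more anchors add precision without
changing the code path. Bars are 1-based and occupy half-open intervals
`[onset_b, onset_{b+1})`. Bars that end up with no samples yield missing
values — never zeros — and the model fitters drop and count those rows.

## Motion, sound, and score features

**Quantity of motion.** Marker trajectories (120 Hz, mm) are differentiated
with a Savitzky-Golay filter of order 3 and window 41; the Euclidean norm
of the three axis derivatives is a speed in mm/s, and QoM is the sum of
speeds over each bar. Speeds are rotation invariant and scale linearly
with the coordinates. The head predictor is the single head marker; the
arm predictor is the *mean* across available arm-marker speeds — a mean
rather than a sum so that unequal marker dropout across performers does
not rescale the predictor (a sum is available via `combine = "sum"`).
Samples with missing positions are masked before filtering; contiguous
valid segments shorter than the filter window are dropped with a log
message.

**Sound level.** Audio is collapsed to mono, cut into 2048-sample frames
with 50% overlap, and summarised as RMS amplitude per frame; the envelope
is smoothed with a 50-sample Hamming window normalised to unit sum (an
unnormalised convolution would rescale the units by the kernel sum) and
averaged per bar using frame-centre times, so a frame's energy is
attributed symmetrically.

**Cloud diameter.** Spelled pitches map to the line of fifths (C = 0, each
sharpward fifth +1, so enharmonic spellings are distinct by construction)
and the line is wound onto a helix with a quarter turn per fifth: position
`(r sin(k*pi/2), r cos(k*pi/2), k*h)`. The cloud diameter of a set of
pitches is the largest pairwise Euclidean distance among their distinct
helix positions, divided by the adjacent-fifth distance `sqrt(2r^2 + h^2)`
so the unit is one perfect fifth. It is a harmonic-tension measure: a lone
pitch class scores 0, `{C, G}` scores exactly 1 for any helix shape, and
transposition (a rigid motion of the helix) leaves it unchanged. Defaults
`r = 1, h = sqrt(2/15)` use the calibrated aspect ratio of the spiral
model; both are exposed because published tools inherit rather than state
them. Per bar, the cloud pools all parts' pitches with onsets in the bar,
plus (by default) notes sustained into it; octave is ignored, and MIDI-style
unspelled input is rejected — spelling is an input contract.

## The mixed models

The per-bar table joins the baseline-differenced pupil mean to the seven
predictors. Model 1 uses head motion; Model 2 uses arm motion instead
(typically on fewer rows, since arm markers drop out more). Each model is

```
pupil ~ cloud + harmonic + qom + sound + technical + expressive
        + (1 | piece) + (1 | subject) + ar1(bar | subject:piece)
```

fitted by maximum likelihood via `glmmTMB`. Within each subject-piece
series the residual covariance is `sigma_ar^2 * rho^|bar_i - bar_j|` plus
an iid nugget `sigma_e^2`; using bar number as the AR(1) time index makes
gaps from dropped bars decay as `rho^gap`. Standard errors come from the
observed information; `z = estimate/SE` with the normal reference, no
degrees-of-freedom correction — consistent with reporting z-values. ML
rather than REML is used throughout because likelihood-ratio tests and BIC
comparisons across fixed-effect structures require it.

Effect sizes are summarised by hierarchical addition: starting from a null
model (intercept, random effects, AR(1) only), significant predictors are
added one at a time in decreasing order of absolute estimate size; each
step reports the df-1 likelihood-ratio chi-square against the immediately
preceding model and the augmented model's BIC (`k log n - 2 logLik`). The
sequential reading is the only one that yields one df-1 statistic per
added predictor.

Between-piece contrasts are fitted per performer with piece as fixed
effect, piece as random intercept, and AR(1) over bars within piece; with
`P` pieces, refitting with bases `1..P-1` collates all `P(P-1)/2` unique
contrasts, flagged at the Bonferroni level 0.008. A contrast `(A, B)` is
the fitted mean difference `B - A`, so swapping the pair flips its sign.

The baseline comparison (first-rehearsal vs pre-concert resting pupil) is
a two-sided Wilcoxon signed-rank test. Zero differences are dropped, tied
absolute differences get average ranks, `W` is the smaller signed-rank
sum, and for up to 50 retained pairs the p-value is exact, computed from
the full distribution of the rank sum over all `2^n` sign patterns (a
convolution over ranks, which handles ties); larger samples fall back to
a tie-corrected normal approximation.

Listener analyses reuse the machinery with listeners as subjects and the
performer-collapsed predictors: ratings and QoM are averaged across
performers at each bar; cloud diameter and sound level are piece-level
series already.

## The synthetic-data generator

The generator emulates the study design: four performers and four pieces,
sixteen listeners, 60 Hz binocular pupil, 120 Hz six-marker motion capture
(head, upper back, two markers per arm), 22.05 kHz audio, per-bar 1–7
ratings, and two-second bars (96 bars per piece by default). Ground truth
lives in a `synth_truth` record: fixed-effect coefficients on the order of
the package's default analysis targets (technical 0.0316, cloud -0.0192,
harmonic -0.0120, expressive 0.0098, head QoM 3e-4 mm per unit, sound 0 as
a null predictor), AR(1) correlation 0.6 with SD 0.08 mm, iid residual
0.04 mm, subject and piece intercept SDs 0.15 and 0.10 mm, resting
baseline 4.0 mm, 15 blinks/min of 0.2 s, and 0.02 mm sample-level
measurement noise. The eye-tracker noise SD is a free parameter, not an
estimate of any device.

Design choices worth knowing:

- **Bar-level signal.** The latent per-bar mean is baseline + fixed
  effects + random intercepts + AR(1) + iid noise; the sample-level trace
  holds it piecewise-constant and low-pass smooths it. The models consume
  only per-bar means, so finer temporal structure is a free choice.
- **Blinks.** Each blink ramps toward zero over two samples, holds, and
  ramps back. The first entry sample is only partially closed — it
  survives the low gate and must be caught by its extreme velocity, giving
  the velocity gate realistic work — while the exit ramp reopens from
  below the low-outlier threshold so the whole episode lands in the gap
  mask and bar means stay unbiased.
- **Closed-loop predictors.** The predictors that drive each synthetic
  pupil trace are the features the package itself extracts from the
  generated motion, audio and score streams (at the analysis settings),
  not the requested calibration targets. This makes the generator the
  exact generative mirror of the fitted model and keeps recovery tests
  free of predictor measurement-error attenuation.
- **Calibration.** Marker paths move on large circles at per-bar angular
  rates chosen so the summed Savitzky-Golay speeds meet the QoM targets
  (within a few percent; the documented tolerance is 10%). Audio is
  uniform noise with per-bar gains solved against the framing-and-
  smoothing mixing matrix measured on indicator envelopes, so the
  extracted sound level recovers its targets through the full chain.
- **Seeding.** All randomness flows from one root seed through named
  substreams (per subject, piece, and stream), so any single stream is
  reproducible in isolation and whole studies are byte-identical per seed.
- **Baselines.** Baseline recordings rest exactly at the truth baseline
  level; per-subject departures from rest live in the subject random
  intercept of the performance trace, so baseline differencing isolates
  exactly the latent predictor signal.

What the generator does **not** emulate: acoustic realism (timbre,
instruments), gaze geometry and luminance effects on the pupil, skeletal
structure in the motion, or musically meaningful scores beyond spelled
pitch clouds. Passing tests therefore demonstrate that the chain measures
what it defines and recovers known parameters under realistic sampling,
noise and blink contamination — not that any particular musical corpus
behaves like the synthetic one.

## Numerical choices and degenerate inputs

- Gate thresholds use strict inequalities; values exactly at 2 SD are
  retained.
- The Savitzky-Golay edge policy refits on the truncated window, widening
  it minimally if fewer than `order + 1` points remain.
- A velocity gate needs spread: a constant series has SD 0 and gates
  nothing.
- `fit_lmm` standardises its fixed-effect columns internally before
  optimisation — predictor scales here span four orders of magnitude (QoM
  in the thousands, sound level below one), which otherwise derails the
  optimizer — and transforms estimates and standard errors back exactly
  (the reparameterisation leaves the maximised likelihood unchanged).
- `fit_lmm` retries a failed optimisation from the first solution with a
  larger iteration budget and then with a BFGS pass; it errors if no
  attempt yields a finite likelihood, and accepts imperfect solutions
  whose information matrix is positive definite, with a warning. Variance
  estimates on the boundary flag the fit as singular.
- Exactly collinear fixed effects are dropped (rank adjustment), so an
  aliased predictor contributes neither likelihood nor a BIC penalty.
- Likelihood-ratio statistics are clamped at zero with a warning if a
  nested fit's log-likelihood decreases by more than 1e-6.
- Empty bars, empty clouds, all-gated traces, and all-zero Wilcoxon
  differences raise errors or missing values rather than silent zeros.

## Problem sizes used by the tests

The unit tests run on toy series (tens to hundreds of samples) against
closed forms and brute-force enumeration. The parameter-recovery check
runs twenty seeded replicates of a full study at 4 performers x 4 pieces x
200 bars (no listeners), fitting the full model plus three single-predictor
models per replicate; coverage of each nonzero coefficient's 95% CI and
the ordering of strong vs null chi-squares are the pass criteria. The
acceptance script runs one complete performer + listener study at the
generator defaults (96 bars, 16 listeners) and reports the fitted
quantities.

## Known limitations

- Bar onsets are interpolated, not aligned to score events; timing error
  within an anchor span biases per-bar aggregation slightly.
- The AR(1) grouping treats each subject-piece series as one stationary
  segment; structural breaks (e.g. movement boundaries) are not modelled.
- Arm-marker pooling, QoM units, and the sustained-note rule for clouds
  are conventions exposed as options; other choices rescale predictors
  (and hence coefficients) without changing test outcomes.
- The Wilcoxon normal fallback (n > 50) uses a continuity correction but
  no exact tie permutation; the exact path covers every realistic baseline
  comparison here.
- `piece_contrasts` fits piece as both fixed effect and random intercept,
  mirroring the analysis design it reproduces; with few pieces the random
  variance is weakly identified and often estimated at the boundary, which
  is flagged but not prevented.
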