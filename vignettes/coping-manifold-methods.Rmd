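---
title: "Methods: scoring, decoding, and manifold alignment of threat-coping dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, decoding, and manifold alignment of threat-coping dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`copingmanifold` analyses single-cell calcium recordings from sessions in
which an animal first rests in its homecage (baseline) and is then suspended
by the tail (TS), an inescapable threat that elicits alternating bouts of
active coping (struggle) and passive coping (immobility). The package covers
four layers of analysis — per-neuron tuning, population decoding, manifold
geometry, and cross-session alignment — plus a synthetic generator with known
ground truth that exercises all of them end to end. This vignette explains
the models and the choices behind them.

## Data model and preprocessing

A session is a z-scored fluorescence matrix (neurons x frames, 20 Hz) paired
with per-frame annotations: context (baseline/TS), coping label
(struggle/immobility/ambiguous, undefined during baseline), and per-body-part
speed traces averaged into a mean speed. Frames are 0-based on disk, windows
are half-open, and second-to-frame conversions round to the nearest frame.
Ambiguous coping frames are stored and excluded explicitly by downstream
operations, never silently dropped.

Preprocessing reproduces the standard post-extraction conditioning for
1-photon data:

* `detrend_percentile()` — subtracts a centered running 10th percentile over
  a 30 s window (edges truncated). This removes slow baseline drift at
  timescales well above the GCaMP6f decay while passing transients almost
  unchanged.
* `zscore_trace()` — per neuron over the full concatenated session, so that
  baseline and TS segments share one scale; scores that compare contexts
  depend on this. Whether the two segments should instead be normalized
  separately is not settled; joint scaling is the default and the functions
  accept pre-split segments if the alternative is wanted.
* `detect_transients()` — flags frames whose increment from the previous
  frame exceeds 2 SD of the trace. We read "increases by more than 2 SD" as a
  condition on the frame-to-frame increment because that is the only reading
  that produces a per-frame boolean of *rising* signal; a level-based
  alternative (`trace > 2`) would flag entire plateaus.
* `smooth_quantile_scale()` — Gaussian smoothing (sigma 250 ms, kernel
  truncated at 4 sigma, reflect padding) followed by a per-neuron monotone
  quantile map onto [0, 1] with 100 anchors, the conditioning used before
  manifold embedding. Rank order is preserved exactly; novel extremes clip
  to [0, 1]; constant neurons map to 0.5 with a warning.

## Per-neuron tuning

**TS selectivity.** Both context segments are concatenated and min-max scaled
per neuron; the score is `(m_TS - m_base) / (m_TS + m_base)` of the scaled
means, in [-1, 1]. Neurons below -0.2 are called baseline-selective, above
+0.2 TS-selective (boundaries exclusive). A transient-based variant applies
the same ratio to transient rates; the rate's time unit cancels, so per-frame
and per-second conventions give identical scores. Zero-range or zero-sum
neurons return a flagged missing value rather than a misleading 0.

**Movement tuning.** The movement score is the Pearson correlation between a
neuron's trace and the mean speed within one context; |r| > 0.2 defines
struggle- (positive) and immobility-tuned (negative) neurons during TS.

**Explained variance.** `movement_ev()` reports mean out-of-fold explained
variance (1 - SSE/SStot) of a univariate regression of trace on speed under
10-fold cross-validation. Folds are contiguous temporal blocks, not shuffled
frames: calcium traces are strongly autocorrelated, and shuffled folds would
leak training information into adjacent test frames and inflate EV.
Significance (`ev_significance()`) circularly shifts the speed trace by a
uniform random offset of 20-120 s, drawn in either direction (the sign is
not specified by convention; symmetric shifts avoid a directional bias), and
declares a neuron significant when its real EV exceeds the 95th percentile
of 1,000 surrogate EVs. `population_ev()` is the same cross-validated EV
with 50 randomly chosen other neurons as predictors.

**Onset lags.** `peth_lag()` builds peri-event windows (0.5 s before to
0.5 s after each coping-bout onset), z-scores neuron data and speed within
each window (the normalization is not standardized anywhere; per-event
z-scoring makes events comparable regardless of amplitude), averages over
events, and cross-correlates the averaged response with averaged speed over
lags of +/-0.5 s. Struggle neurons take the correlation argmax, immobility
neurons the argmin; a lag is significant when its correlation deviates from
the same-type population mean by more than 1 SD, and significant negative
lags are "early" (activity precedes behavior). With a single analyzed neuron
the population SD is undefined and the result is flagged instead of
classified.

## Decoding

All decoders work on balanced frame sets: every frame of the minority class
plus an equal-sized uniform random subset of the majority class, kept in time
order. Folds are contiguous blocks over that set (same autocorrelation
argument as above), and every paired comparison — real vs surrogate,
condition A vs B, day d vs d' — reuses the identical fold partition, which
`compare_to_null()` enforces by comparing fold indices. Standardization is
fit on training folds only and applied to test folds; the literal
whole-dataset variant would leak test statistics into training, so
fit-on-train is the default.

Models and regularization: logistic regression with inverse strength C = 0.1
for context and C = 0.01 for coping (mapped onto glmnet's penalized
likelihood via lambda = 1/(C n)), linear SVC (cost 1), ridge classifier and
ridge regression (penalty 50, exact closed form with unpenalized intercept),
and Gaussian naive Bayes. Binary tasks report mean fold accuracy; speed
decoding reports the mean per-fold Pearson correlation between predicted and
true speed. Chance is estimated from circular-shift surrogates — each
neuron's trace rotated by an independent uniform offset — which preserve
every neuron's marginal distribution and autocorrelation exactly while
destroying its timing relative to behavior and to other neurons.

Cross-condition speed decoding trims the longer context to the shorter one's
length (dropping the tail) and applies one fold template to both segments;
the within-condition case reduces bit-for-bit to plain speed decoding.
Across-day decoding uses only neurons registered on all days (rows matched
by global id), balances within each day, equalizes frame counts across days,
and trains on day 1 with the shared fold template.

## Manifold geometry and alignment

TS-segment traces are smoothed, quantile-scaled, and embedded in 5
dimensions. The default method is isomap (Euclidean kNN graph, 500
neighbours at full scale; graph geodesics; classical MDS). The model is fit
on an evenly strided 60% subset of frames — a stride, not a random subsample,
so the landmark set covers the session uniformly and refitting is
deterministic — and all frames are then embedded by landmark MDS, with
geodesics from a new frame approximated through its 20 nearest landmarks
(training frames recover their fit coordinates exactly because they are
their own nearest landmark at distance zero). A disconnected neighbourhood
graph is an error advising a larger neighbourhood. PCA and spectral
embeddings are fit on the full data.

Trajectory structure is characterized on a 2-d plane: velocity vectors
binned on a 15 x 15 grid (flow field, including each bin's mean radial
component about the origin), and turn angles of the trajectory mean-binned
to 2.67 Hz, with angles in (0, pi) counted as leftward turns. The bin count
follows from the segment length and the target rate rather than being fixed,
so shorter sessions keep the same temporal resolution. `select_plane()`
automates what is otherwise a visual choice: it scores every axis pair by
directional consistency (net signed share of leftward turns) weighted by
turn-angle concentration and returns the best pair, breaking exact ties
toward the lowest axis indices.

For alignment, each manifold is centered and divided by its Frobenius norm.
The norm is global, not per dimension: per-dimension scaling would distort
the relative variance structure that the orthogonal transform is supposed to
preserve (a per-dimension variant is a one-line change if wanted). Template
manifolds rescale every struggle and immobility epoch to 20 progression
digits and average per digit per dimension over all epochs of a class,
pooling frames (so long epochs weigh by their frame count within a digit);
with 5 embedding dimensions every template is 5 x 40. Epochs shorter than 20
frames contribute via nearest evenly spaced positions; epochs shorter than 2
frames are excluded; a digit with no frames at all is an error naming the
digit.

The orthogonal Procrustes problem `argmin ||A Q - B||_F` over orthogonal Q
is solved in closed form: `t(A) %*% B = U S t(V)` with singular values
decreasing, `Q = U t(V)`. Templates are stored dimensions x time but
transposed to time x rows for the solve, since a d x d transform acting on
the right requires time along rows. Q is allowed to include a reflection
(it is an orthogonal, not special-orthogonal, solution); the random-rotation
null, by contrast, draws Haar-uniform matrices with determinant +1, which is
the stated form of that control. A rank-deficient cross-product still
returns a valid Q but warns that the optimum is not unique. The aligned full
manifold is `M %*% Q`; orthogonality guarantees pairwise distances are
untouched.

Cross-manifold decoding trains on the reference manifold's coordinates and
behavior and predicts from the aligned target manifold, with an equal number
of struggle and immobility frames within and between the two datasets and
one fold template shared by the within-reference, aligned, random-rotation
(100 repetitions), and shuffle variants. The shuffle control circularly
shifts each neuron before the whole embed-template-align path is rerun; the
reference manifold is always kept fixed. Cross-animal analyses pair animals
circularly: each animal is predicted from its predecessor, the first from
the last.

## The synthetic generator

The generator emulates the statistical structure the analyses assume, so
that every stage can be validated against ground truth without any recorded
data:

* Behavior: a baseline segment followed by TS tiled with alternating
  lognormal struggle/immobility bouts (mean struggle bout 4 s, sdlog 0.6).
  Bout durations are rescaled so the day's target immobility fraction is met
  exactly up to frame rounding; the schedule (0.4, 0.6, 0.6 for days 1, 3,
  9) emulates the habituation-like rise of passive coping. Two frames on
  each side of every transition are labeled ambiguous. Speed is a smooth
  high-mean process during struggle (6 cm/s), near zero during immobility,
  and an independent moderate process during baseline (2 cm/s).
* Latent state: a planar ring whose phase advances 0 to pi across each
  struggle epoch and pi to 2 pi across each immobility epoch, plus
  white-noise nuisance dimensions. Phase and radius jitter are temporally
  smooth (0.5 s kernel, marginal SDs 0.1 rad and 0.05): white per-frame
  jitter would exceed the per-frame phase advance and destroy the one-way
  rotation the trajectory statistics measure.
* Neurons: rate = `rate_hz * softplus(loadings . latent + beta *
  speed_TS / 4) / softplus(0) * gain^[TS]`, Poisson events with lognormal
  amplitudes, an exponential kernel with tau = 0.6 s (GCaMP6f-like decay),
  additive Gaussian noise, and session-wide z-scoring. The softplus-linear
  link is the simplest model producing calcium-like asymmetric transients
  with controllable SNR. Context-selective neurons carry gains of 3-6
  (TS-preferring) or 1/6-1/3 (baseline-preferring); movement-tuned neurons
  couple to TS speed only, with coefficients of +/-(1.2-2.5) against ring
  loadings of SD 0.25 — the regime in which movement scores are governed by
  the movement coefficients rather than by ring loadings, which is what the
  tuning-recovery validation requires. Noise SD 0.03 on unit transients and
  ~2 Hz event rates describe a well-denoised source-extraction output; these
  are mid-range choices, not fits, since no SNR statistics are available to
  match.
* Days and animals: per-day presence is i.i.d. Bernoulli(0.74), so about
  0.74^3 = 41% of neurons appear on all three days; present neurons keep
  their loadings up to 5% multiplicative jitter, and the registration table
  reflects presence exactly. Cohort animals share the behavior-to-phase law
  but receive independent neurons whose loadings act through per-animal
  Haar-random orthogonal mixing of the latent, which is what makes
  cross-animal alignment nontrivial. A day-to-day mean-activity drift knob
  exists and defaults to off.

What the generator does not emulate: imaging movies and their artifacts,
neuropil contamination, registration errors (the ground-truth table is
exact), nonstationary tuning within a session, and any coupling between
baseline movement and neural activity. Passing tests therefore demonstrate
that the pipeline recovers the structure it assumes when that structure is
present and cleanly registered — not that real recordings satisfy those
assumptions.

One property of the softplus link is worth knowing: because the link is
convex, neurons with strong movement coefficients of either sign have a
higher mean rate during struggle (when `|beta| * speed` is large and
variable) than during immobility. This class-mean signature is shared by
movement-tuned neurons of *any* session, so a decoder trained on one day
retains a residual above-chance margin on a day with completely
re-randomized loadings (about 0.69 accuracy in the ablation test, against
0.95 with stable loadings). The ablation still separates the two regimes
sharply; the residual margin is a property of the link, not a leak in the
cross-validation.

## Numerical choices and degenerate inputs

Orthogonality and idempotence checks use 1e-10; exact-recovery checks 1e-8.
Quantile maps collapse duplicated anchors to stay functions. The running
percentile uses type-7 quantiles with truncated edge windows. Zero-variance
traces, constant decoding folds, single-class training folds (re-balanced
with a logged retry), empty coping epochs, all-identical manifolds, and
rank-deficient Procrustes systems all produce explicit errors, warnings, or
flagged missing values rather than silent results. All randomness flows from
one master seed through fixed per-stage offsets, and every seeded function
restores the caller's RNG state.

## Problem sizes

The validation suite runs the tuning and decoding calibrations at the study
scale (200 neurons, 12,000 baseline + 12,000 TS frames). Manifold analyses
in the tests use 100 neurons, 4,000 TS frames and 100 isomap neighbours —
the embedding, templates, and alignment behave identically at this scale
while geodesic computation stays light; at full scale the defaults (500
neighbours) apply unchanged. Surrogate calibrations use 200 neurons with 200
surrogates each. The same sizes are used by `scripts/acceptance.R`.

## Interface

The package is function-first: `generate_cohort()` / `generate_multiday()`
for data, `preprocess_session()`, `tuning_table()`, `decode_binary()` /
`decode_speed()` / `across_day_decode()`, `ts_manifold()` /
`cross_manifold_decode()`, and `run_study()` to orchestrate everything into
a JSON-serializable report. Sessions travel as HDF5 files
(`write_session()` / `read_session()`) and registration tables as CSV with
-1 marking absence.

## Known limitations

Isomap's out-of-sample geodesics are approximated through the 20 nearest
landmarks; pathological geometries could route a shorter path through a
non-neighbour. The spectral embedding builds a dense Laplacian and is meant
for moderate frame counts. The shuffle null preserves single-neuron
autocorrelation, so on strongly bout-structured synthetic data it can sit
somewhat above 0.5 even though it removes all cross-neuron timing. And the
generator's selectivity and movement partitions are drawn independently, so
a neuron can be both baseline-selective and struggle-tuned; its net context
effect is then genuinely small, which is why recovery checks condition on
the rate-level oracle effect size rather than on the gain label alone.
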