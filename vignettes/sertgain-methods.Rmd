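---
title: "Methods: separable gain analysis of ongoing and evoked V1 activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: separable gain analysis of ongoing and evoked V1 activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sertgain)
```

## The experimental design being modeled

One trial of the core design lasts 30 s at a 100-Hz frame rate and comes in
four conditions: a visual stimulus train (V; ten 200-ms gratings at 3-s
intervals, the first 200 ms after recording onset), the same train with
optogenetic photostimulation of serotonergic neurons (V_ph; a 16-s,
20-Hz pulse train starting at 2.5 s), and the two spontaneous analogues
(S, S_ph) with a blank screen. A second design presents a single grating at
one of five contrasts (100, 50, 25, 12.5, 6.25%), with photostimulation
beginning 700 ms before the grating and lasting to the end of the trial.
Both designs are captured by `protocol_spec()`; time is seconds throughout,
frames are indexed from the start of recording, and every analysis window is
half-open `[t0, t1)`, converted to frames by flooring `t0·rate` and ceiling
`t1·rate`. That convention is deliberate: it makes window arithmetic exact
and testable (a 400-ms window at 100 Hz is always 40 frames).

## The generative model behind the synthetic data

The synthetic-data module is not a test fixture but the package's
operational definition of the hypotheses under test. The ROI-level signal of
one trial is

```
x(t) = spont(t)·G_s(t) + offset(t) + evoked(t)·G_e(t) + late(t)
```

* `spont(t)` — a stationary Ornstein-Uhlenbeck process (exact AR(1)
  discretization; marginal SD `std`, default 0.01 delta-F/F; correlation
  time 2 s). It was chosen over white noise because ongoing wide-field
  activity is dominated by slow fluctuations, and because the OU process has
  closed-form moments, so trial averages and window variances can be
  asserted analytically in tests.
* `G_s`, `G_e` — gates equal to 1 outside the photostimulation window and to
  the gains `g_s`, `g_e` inside it. Divisive suppression of ongoing activity
  acts on the *fluctuations* (`G_s` multiplies the zero-mean process, so it
  is visible in variances and in firing rates, not in the mean of a zero-mean
  imaging trace); `offset(t)` carries the additive baseline shift of the
  imaging signal during photostimulation.
* `evoked(t)` — a difference-of-exponentials calcium kernel (unit peak)
  convolved with the stimulus onsets and scaled by the Naka-Rushton response
  at the condition's contrast. Kernel defaults place the response peak at
  443 ms after stimulus onset in the anesthetized regime
  (`rise_tau` 0.25 s, `decay_tau` 0.9 s) and 294 ms in the awake regime
  (0.15 s, 0.7 s), reflecting the earlier awake peak.
* `late(t)` — a slow linear ramp starting 6 s into the photostimulation
  window (slope 0.002 delta-F/F per s), standing in for intracellular
  calcium accumulation. It is added to the imaging signal only, never to the
  spike-count rates: the dissociation between the calcium and spiking
  read-outs is structural in the generator, and a test asserts it.

Movies embed `x(t)` in a vignetted illumination map with a central disk as
the responsive region, add global heartbeat (10 Hz) and respiration (3 Hz)
sinusoids (mouse physiology; the frequencies are package choices since only
the artifact types are given by the protocol), a 20-Hz square-wave
photostimulation artifact confined to the lower-left corner block, and
per-pixel Gaussian noise (1% of the illumination level). Spike counts are
Poisson draws of `base_rate·G_s·(1 + evoked_rel·G_e) + offset` with unit base
rates drawn from 0.5–25 Hz, chosen to exercise both rate filters (the
below-1-Hz exclusion and the 1–20-Hz band).

Regime defaults (`ground_truth(state = ...)`) encode the two cortical
states: anesthetized `g_e = 0.52`, `g_s = 0.6`, offset −0.02 delta-F/F;
awake `g_e = 0.78`, `g_s = 0.65`, offset −0.01. Antagonist variants are
parameter sets, not pharmacology: the 5-HT2A blocker variant sets
`g_e = 0.9` and attenuates the late ramp; the 5-HT1A blocker variant sets
`g_s = 1` and offset 0.

What the generator does *not* emulate: hemodynamic contamination, motion,
vascular structure, single-cell heterogeneity, adaptation across the
stimulus train, and any biophysical indicator kinetics beyond the linear
kernel plus ramp. Tests passing on this generator therefore certify the
analysis chain (estimators recover the parameters that generated the data),
not the biological adequacy of the model.

All randomness derives deterministically from one master seed per
ground-truth object; per-trial seeds are hashed from (seed, condition,
trial), so any single trial can be regenerated in isolation and conditions
can deliberately share spontaneous draws (`noise_stream`) to emulate
paired-trial designs or to make identity checks exact.

## Preprocessing

The order is fixed and logged: delta-F/F, optional ICA artifact rejection,
spatial filtering, ROI averaging.

* **delta-F/F.** Each pixel is divided by its mean over the first 200 ms,
  the mean pre-stimulus-normalized blank (S) movie is subtracted
  frame-by-frame, and the result is divided by the pixel's temporal mean of
  that blank reference. Normalizing the blanks by the same pre-stimulus rule
  *before* averaging is a package choice among ambiguous orderings; it was
  picked because it makes the identity case (stack equal to blank) yield
  exactly zero.
* **ICA rejection** (off by default, fully logged). Temporal independent
  components are extracted per trial by JADE and rejected when at least half
  of their power above 0.5 Hz falls within ±0.5 Hz of a target band
  (heartbeat, respiration, 20 Hz). Two numerical choices matter here.
  First, JADE rather than fastICA: with few genuine sources and many
  near-Gaussian noise directions, fastICA's deflation splits a gated square
  wave across components, while joint diagonalization keeps it intact at low
  model order — but *which* order isolates it varies by trial, so the model
  order is swept from 2 to 6 and every flagged component is pooled. Second,
  removal is implemented as regression of the pooled artifact time courses
  out of every pixel (through an orthonormal basis), which also removes the
  cross-terms that zeroing a mixing-matrix column would leave behind. The
  band-fraction denominator excludes power below 0.5 Hz because the gate
  envelope of a photostimulation-locked artifact otherwise dilutes its own
  20-Hz signature.
* **Spatial filtering.** Frames are Gaussian-smoothed (sigma in pixels) and
  high-pass filtered with a radial Butterworth magnitude response of order 4
  and cutoff `1/33` cycles/px, both applied in the spatial-frequency domain
  (periodic boundary), so the response at the cutoff is exactly `1/sqrt(2)`
  and the DC of every frame is removed. The "33 pixels" figure is read as a
  cutoff *wavelength*; since a temporal reading of the filter is also
  defensible, `temporal_filter()` implements a zero-phase temporal
  Butterworth and `preprocess_trials(butter_domain = "time")` switches to
  it. The spatial reading is the default. On simulated images smaller than
  the acquisition format, the smoothing sigma is scaled down accordingly
  (the pipeline default uses sigma 1–2 px on 10–16 px images); the
  acquisition-scale defaults (sigma 20 px, cutoff 33 px) remain the
  documented function defaults.
* **ROI selection** automates what is otherwise a manual step: threshold the
  trial-averaged control evoked map at 70% of its maximum and keep the
  4-connected component containing the first-scanned (row-major) maximum —
  a deterministic tie-break asserted by a two-blob test.

## Components, windows and metrics

Per-stimulus peak times are located on the *control* condition (maximum
within 1 s after onset, earliest sample on ties) and reused for all other
conditions of the dataset, so the 400-ms peak window `w1` and the 200-ms
pre-onset baseline window `w2` are identical across conditions — a
prerequisite for paired comparisons. The 1-s search bound holds the peak
without clipping slow responses, given kernel peaks in the 300–450 ms
range. Amplitude is the mean over `w1`, baseline the mean over `w2`, and
magnitude `|amplitude − baseline|` — the baseline-independent response-gain
measure on which the whole gain analysis rests (magnitude is invariant to
adding any constant to a trace, which a test asserts exactly).

The evoked component is isolated by trialwise subtraction
`E_ph,i = V_ph,i − S_ph,i`, pairing trials by index when counts match
(conditions are interleaved within trials) and falling back to subtracting
the S_ph mean otherwise; the fallback is recorded. Multi-unit traces follow
their own normalization path: spontaneous conditions are divided by the
unit's mean over the first second; evoked conditions have that mean
subtracted and are then divided by the first-stimulus control amplitude.

## Suppression regression

The pre/post records feed an ordinary least-squares fit of
`fr_post ~ ph * fr_pre` after normalizing all rates by the maximum
pre-window rate across units — a normalization that rescales the intercept
terms but provably leaves the slope terms unchanged (asserted to 1e-10).
Units below 1 Hz are excluded by default to avoid floor effects; the
1–20-Hz band is available as the `"band_1_20"` preset. The default
stimulus-train protocol places photostimulation at 2.5 s, so a 4-s pre
window does not fit; `build_prepost()` rejects it and the pipeline uses
`min(4, onset)`. Cohorts are summarized by subject-level fits followed by
across-subject one-sided one-sample t tests on `b2` and `b4` (the
mean-±-SEM-of-coefficients reading of the design; a pooled fit is a
caller-side option by concatenating records), classifying suppression as
divisive, subtractive, mixed, or none. With fewer than three subjects the
tests are skipped and the label is flagged untested.

The record-level cohort simulator used for classification tests operates on
the normalized-rate scale of the regression itself (pre-rates uniform on
[0.05, 1], `post = g_s·pre + offset + noise`): an offset stated on this
scale is the quantity `b2` estimates, whereas a −0.1 Hz offset on raw
Poisson rates would be invisible at realistic cohort sizes.

## Contrast tuning

Naka-Rushton fitting uses bounded Levenberg-Marquardt least squares with
multi-start: `R0 = min(peaks)`, `R_max = max − min`, `c50 = median
contrast`, `n` started from {1, 2, 4}; bounds `R_max ∈ [0, 10·range]`,
`c50 ∈ [0.01, 1]`, `n ∈ [0.1, 10]`, `R0` free. Multi-start plus bounds make
convergence a testable property rather than a hope; flat data are fitted as
an offset and flagged degenerate. `r_squared` is reported whenever at least
one residual degree of freedom exists (five contrasts minus four parameters
leaves one) and `SS_tot > 0`; otherwise it is `NA`.

The normalization test scales each condition's peaks by its own
100%-contrast value and refits. Two routes are compared: raw peak
amplitudes of V_ph (which retain any baseline shift) and the
evoked/spontaneous decomposition route (E_ph magnitudes, i.e. the
`E_ph + S_ph` account of V_ph with the spontaneous level measured
separately). Under pure response gain both collapse onto control; with an
added baseline shift the amplitude route deviates most strongly at the
lowest contrasts while the decomposition route still collapses — the
package's operational version of the normalization-dissociation analysis.

Latency is the first time after onset at which the trace exceeds the
pre-onset (700 ms) mean plus twice its SD for at least two consecutive
samples; the two-sample persistence rule is a package choice to resist
single-frame noise. Duration is the total time above half of the peak
within the stimulus window.

## Gain decomposition

`g` is estimated from magnitudes, not amplitudes, because magnitudes are
invariant to the baseline shift and therefore isolate the evoked gain; a
pooled estimate uses the 100%-contrast ratio, and per-contrast estimates
are also reported since the single-ratio reading of the model is ambiguous.
The baseline weight `g·S_ph` is reported both at the control peak time and
averaged over the photostimulation window (the analysis uses both). On a
noiseless linear construction `V = g(E_ph + S_ph)` the decomposition is
exact to numerical precision, which the test suite asserts at 1e-6.

## Statistics

The permutation correction is max-statistic sign-flip (Westfall-Young
style): flip each pair's sign independently, record the family maximum of
the (signed, for one-sided tests) t statistic, and declare a member
significant when its observed statistic exceeds the (1−alpha) quantile of
that null maximum distribution. All 2^n sign patterns are enumerated
exactly while `2^n ≤ 4096`; beyond that, 10,000 Monte-Carlo flips with a
logged seed. Sign-invariance of the sum of squares reduces each permutation
to a matrix product, so exhaustive enumeration is cheap. Corrected p-values
are never smaller than the member-wise permutation p (asserted), and the
familywise error rate under a global null is checked by simulation against
the binomial 99% interval around alpha.

Degenerate t-test inputs follow fixed conventions: zero variance with zero
effect gives p = 1; zero variance with a nonzero effect gives p = 0 with a
degenerate flag. Onset-of-significance detection requires the criterion
(per-bin corrected paired test, or 2 SD below the pre-photostimulation
reference) to hold for two consecutive bins. The detrended two-sample
comparison fits each trace's linear trend over the full window but compares
residuals over the central half: per-trace residuals average to zero over
the fitting window by construction, so a full-window mean comparison would
be vacuous — the fit/test split is what makes the procedure sensitive to
mid-window shape differences while exactly-linear inputs still return
p = 1.

## Problem sizes and reproducibility

The default pipeline configuration simulates 3 subjects, 4 conditions and
6 trials per condition as 16x16-pixel movies at the full 100 Hz/30 s
protocol, plus 24 units x 15 trials of spike counts and 20-trial ROI-level
contrast series — sizes chosen so a complete simulate-analyze-report cycle
runs in well under a minute while every estimator still operates in its
intended regime. Unit tests use 8-12-pixel movies and shortened protocols;
recovery tests state their own trial counts. All outputs are plain CSV/JSON
written with full numeric precision, and a run log records package version,
seed and configuration; repeated runs at one seed are byte-identical, which
both the test suite and the acceptance script verify.

## Known limitations

* The generator's late calcium ramp is linear with free onset and slope;
  no quantitative description of the real phenomenon is encoded, so ramp
  parameters should be treated as qualitative.
* ICA rejection assumes artifacts are temporally separable sources; a
  photostimulation-locked *neural* response shares the artifact's gate
  envelope, and only the oscillatory 20-Hz signature distinguishes them.
* The suppression regression is plain OLS per subject; no hierarchical
  pooling is attempted.
* Contrast is the only stimulus dimension; orientation and spatial
  frequency tuning are out of scope, as are motion correction, hemodynamic
  correction and cross-session registration.
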