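---
title: "Methods: simulating and analyzing subthalamo-cortical beta dynamics during continuous wheel turning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing subthalamo-cortical beta dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and scientific background

`betawheel` implements a complete analysis chain for studying oscillatory
dynamics in the basal ganglia–cortex loop during continuous rotational
movement with starts, reversals, and stops, cued either predictably (fixed
order and 4 s spacing) or unpredictably (0–2 reversals per trial, jittered
inter-stimulus intervals). The recurring electrophysiological motifs the
package targets are movement-related **beta suppression** (13–30 Hz power
falling below baseline around movement onset), the **beta rebound**
(transient increase after movement termination), movement-start **gamma**
increases in the contralateral subthalamic nucleus (STN), and **directed
cortex→STN beta coupling**.

Because intracranial patient recordings of this kind cannot be
redistributed, the package ships a synthetic-data generator whose ground
truth is fully known, and every analysis stage is validated against that
truth. The generator is first-class, tested code — not a fixture.

# The synthetic cohort generator

## Task sequences

`task_config()` / `generate_task_sequence()` produce cue tables. The
predictable block is strictly periodic: start, reverse after 4 s, stop
after another 4 s, then a 4 s pause. The unpredictable block draws the
reversal count per trial from {0, 1, 2} with equal probability and draws
each inter-stimulus interval from a mixture holding 50% of intervals at
4 s and spreading the rest uniformly over 4–7 s. The post-stop pause in
the unpredictable block is drawn from the same mixture, so no interval in
that block is informative beyond the mixture itself (a property-style test
checks that the ISI sequence carries no serial structure).

## Wheel kinematics

`generate_wheel_trace()` integrates a piecewise angular-speed profile:
raised-cosine ramps (default 0.15 s) between rest and the steady turning
speed (default 400 deg/s), a brief zero-speed dwell at each reversal
(default 0.2 s), and deceleration to zero at stop. Movement onset for each
cue is the cue time plus a reaction time drawn from a truncated normal
whose condition-specific means and SDs default to the group values used
throughout the package (predictable start 0.757 ± 0.154 s, unpredictable
start 0.840 ± 0.160 s, predictable stop 0.824 ± 0.202 s, unpredictable
stop 0.889 ± 0.233 s); reversal reaction times are free parameters set
between those values. The resulting angle is quantized at the encoder
resolution (default 0.1°). Ground-truth events are defined as: start =
speed onset; reversal = center of the zero-speed dwell; stop = the moment
speed first returns to zero.

## Neural signals

Each channel is a sum of

* a 1/f^α background (`pink_noise()`, spectral synthesis with the
  spectrum flattened below 1 Hz so the process has no drift), and
* band-limited stochastic oscillations: white-noise-driven damped
  resonators (AR(2) processes, `ar2_series()`) with configurable center
  frequency and bandwidth (beta: 20 Hz, 3 Hz; gamma: 70 Hz, 10 Hz).

Event-locked modulation multiplies an oscillation's amplitude envelope by
the square root of a configured power gain over a window anchored to the
ground-truth event, with 0.1 s cosine edges. The default envelope depths
(start suppression −3 dB contralateral / −1.5 dB ipsilateral, stronger in
the predictable condition; stop rebound +2.5 dB contralateral / +1.0 dB
ipsilateral; brief ±1 dB reversal modulations; +2 dB gamma at start in
the contralateral STN) are **free generator parameters with known ground
truth, not empirical values** — all recovery tests compare against the
configured truth, never against published dB values.

Directed coupling adds a lagged (default 10 samples = 20 ms), scaled
(default 0.65) copy of the source channel's band-limited component to the
target, so influence is strictly causal source→target. The default
configuration couples M1→STN within each hemisphere, with the post-stop
coupling gain raised in the unpredictable condition, emulating
predictability-dependent coherence modulation.

Contralateral/ipsilateral channel roles are resolved to physical
hemispheres from each synthetic subject's moving-hand metadata; hands
alternate across the cohort.

## Implied (measurable) ground truth

The measurable post-minus-pre dB modulation differs from the nominal
envelope depth: the 1/f background contributes unmodulated in-band power
(kept near 2–4% of the oscillation power by default), the sliding
analysis window smears the envelope in time, the multitaper bandwidth
smears it in frequency, and dB values are averaged per bin rather than
computed from window-total power. `implied_band_modulation()` emulates
the estimator analytically (envelope convolved with the window's taper
energy profile, spectra smoothed over the half-bandwidth, per-bin dB
against the per-frequency baseline mean), and `implied_coherence()` does
the same for the shared-signal coherence including the phase rotation the
transmission lag induces across the smoothing bandwidth. Recovery tests
compare estimates to these implied values, which is exact rather than
approximate bookkeeping.

## What the generator does not emulate

No volume conduction or sensor-space mixing, no head geometry, no tremor
or movement artifacts, no line noise, no non-stationarity beyond the
event-locked envelopes, and no state-dependent beta (the suppression is
an event-locked window, not a function of ongoing speed). Passing tests
therefore demonstrate correctness of the estimators and inference under
this generative model, not robustness to every property of real
recordings.

# Kinematic analysis

`angular_speed()` takes the central finite difference of the encoder
angle and smooths it with a 50 ms moving average — enough to suppress
quantization noise (0.1° steps at 500 Hz otherwise produce ~10 deg/s
speed noise) without blurring reversals.

`detect_events()` operationalizes semi-automated event marking with an
event-specific combination of amplitude and duration thresholds (defaults:
50 deg/s, 0.3 s — robust for the default 400 deg/s turning speed). Raw
threshold crossings lag movement onset by tens of milliseconds on a
smooth ramp, so each crossing is refined: starts walk back, and stops walk
forward, to a noise floor (15% of the amplitude threshold); reversals are
placed at the midpoint of the sub-threshold interval between
opposite-sign supra-threshold flanks, which coincides with the
zero-crossing center for a symmetric reversal. Events violating temporal
ordering are dropped with a logged reason — a deterministic, reproducible
stand-in for manual correction. With these defaults, detection on
generator output reaches ≥ 0.99 sensitivity with mean timing error well
under 20 ms (verified by the test suite).

Epochs are 4 s windows centered on events (or linked cues), half-open
`[t0, t1)`, with out-of-bounds trials excluded and counted. Reaction time
is event time minus linked-cue time; negative values are flagged and
excluded.

# Spectral analysis

Slepian tapers are computed from the symmetric tridiagonal form of the
spheroidal concentration problem; the time–bandwidth product follows the
taper count via NW = (K+1)/2, so 4 tapers in a 0.8 s window give a
±3.125 Hz half-bandwidth and 7 tapers ±5 Hz.

The time-frequency decomposition uses 0.8 s windows stepped by 50 ms over
−1.6 to 1.6 s, a low band (5–45 Hz, 4 tapers) and a high band (55–90 Hz,
7 tapers) that skip 50 Hz line noise, and the window's natural Rayleigh
frequency grid (1.25 Hz spacing). Windows that would extend beyond the
epoch are not computed (no padding), which is exactly why ±2 s epochs
yield the ±1.6 s analysis span. Each window is demeaned before tapering.
Power is `|X|²` averaged over tapers (and trials); across-trial coherence
pools trials × tapers as observations,
`|Σ X Y*| / sqrt(Σ|X|² Σ|Y|²)`, and needs at least two observations.
Baseline correction uses the −1.6–0 s pre-event window: dB for power,
subtraction for coherence. Band summaries average 13–30 Hz (beta) or
55–90 Hz (gamma) over pre (−1.6–0 s) and post (0–1.6 s) windows, with
modulation defined as post − pre; channel/ROI selection and the Granger
stage instead use whole-segment spectra over ±2 s windows
(`segment_band_modulation()`).

# Non-parametric spectral Granger causality

Cross-spectral densities for the post-event 0–2 s window pool trials and
15 tapers (±4 Hz smoothing), which stabilizes the factorization at a few
dozen trials. Three numerical choices matter here, and all three were
driven by observed convergence behavior on band-limited 1/f-background
spectra:

1. **Frequency oversampling.** The cross-spectrum is computed on a
   zero-padded grid (factor 6). The minimum-phase factor of a sharp beta
   resonance has long temporal memory; on the bare grid the causal
   support available to the factorization cannot hold it and the
   iteration hits a reconstruction floor far above tolerance.
2. **Causal projection.** After each Wilson–Burg update the factor is
   projected back onto its causal support; circular frequency-domain
   products otherwise leak anticausal energy and the iteration enters a
   limit cycle instead of converging.
3. **Iteration budget.** The tolerance is a relative Frobenius
   reconstruction residual of 1e-8 with up to 500 iterations;
   non-convergence is an error carrying the residual, never a silent
   acceptance. Typical estimated spectra converge in 30–60 iterations.

Geweke's directed measure is computed from the factorized transfer
function and innovation covariance, band-averaged over the same beta and
gamma ranges as power. The time-reversal contrast reruns the full
pipeline on sample-reversed trials; genuine lagged influence yields a
positive original-minus-reversed difference for the true direction and a
negative one for the reverse, so directionality is read from the sign.
The pointwise Geweke spectrum can exceed the total interdependence at
isolated frequencies — a known property of the measure — so sanity bounds
are enforced on integrated values only.

# Cluster-based permutation inference

Group inference on baseline-corrected maps uses a one-sample t per bin
across subjects, a two-sided cluster-forming threshold at α = 0.05
(|t| > t₀.₉₇₅, df = N−1), 4-neighbor adjacency on the freq × time grid
(the conservative, simplest choice), the sum of t values as cluster
statistic, and a permutation null of the per-sign maximum |t-sum| under
random per-subject sign flips, 1000 draws with the observed included
(so p ≥ 1/1000). Significance is α = 0.05 split across tails (0.025 per
sign). Subjects are the permutation unit, mirroring group-average
figures with significance contours; a trial-level variant is not the
default.

One consequence worth spelling out: with n subjects there are only 2ⁿ
sign patterns, so no cluster can ever reach p ≤ 0.025 unless
2^(n−1) well exceeds 2/α. Eight subjects (best achievable p ≈ 0.008) is
the smallest comfortable cohort for this test; the reduced validation
suites use exactly that.

# Behavioral and band statistics

Paired t tests report one- and two-sided p values from the t
distribution and the paired effect size d = t/√n; partial eta squared
follows the identity F·df₁/(F·df₁ + df₂). Both identities reproduce every
printed (t, d) pair and (F, df, ηp²) triple of the study the package
models, which the acceptance suite checks to three decimals (half away
from zero). The repeated-measures ANOVA is the univariate within-subject
decomposition (each effect against its effect-by-subject stratum) via
`aov`; the multivariate sphericity-robust tests and the
covariate-adjusted ANCOVA of the original analysis (age, clinical scores,
disease duration, turning speed as covariates) are deliberate non-goals —
covariate adjustment requires the real cohort, and printed F tests with
covariate-reduced error degrees of freedom are reproduced only through
the ηp² identity, not from data.

The lateralization index is (|contra| − |ipsi|) / (|contra| + |ipsi|) of
baseline-corrected band modulations. Magnitudes are used because the
ratio is otherwise ill-defined for negative dB values; the sign
convention makes contralateral dominance positive, 0 bilateral, and the
index antisymmetric under swapping hemispheres. Opposite-sign inputs are
flagged with a warning; two zero modulations return `NA`.

# Channel and ROI selection

Bipolar re-referencing takes differences of adjacent contacts. The
analyzed LFP channel is the bipolar candidate maximizing
|suppression| + |rebound| of whole-segment beta modulations (equal
weights — both criteria are stated, no weighting is, and equal weights
are the symmetric default), with deterministic ties broken by label
order, and candidate trials pooled across predictability conditions.
Cortical grid points are selected by the largest |post − pre| beta
contrast (±2 s segments) averaged over subjects and the three event
types — absolute values, so suppression- and rebound-dominated
candidates compete on equal footing — and a region of interest is the
peak plus its 6 nearest grid neighbors.

# Pipeline, reproducibility, and problem sizes

`run_full_analysis()` sequences simulation, detection, spectral
estimation, cluster inference, Granger contrasts, and group statistics,
writes CSV/JSON artifacts, and (for synthetic cohorts) compares
estimates against the generator's implied truth
(`validate_against_truth()`). All randomness flows from a single seed;
per-stage seeds are derived deterministically, so identical
configurations are bit-reproducible.

The full study layout is 20 subjects × two 36-trial blocks per condition.
The test and validation suites run reduced sizes chosen for statistical
adequacy at practical runtimes: 200 null datasets of 20 subjects for
type-I error, 100 replicate cohorts of 8 subjects × 8 trials for
detection power (the 8-subject floor is the sign-flip argument above),
100 coupled 40-trial datasets for direction recovery, 300 trials per
condition for kinematic recovery, and a 10-subject × 12-trial cohort for
parameter recovery. On-disk persistence uses plain-text containers (CSV
arrays and tables, JSON metadata, YAML configuration).

# Known limitations

* The generator's event-locked envelopes are independent across events;
  sustained movement states and their interaction with baseline windows
  are not modeled.
* Granger analysis is bivariate by design; conditional or blockwise
  variants, phase-slope index, and partial directed coherence are
  non-goals.
* No wavelet or Hilbert-envelope spectral alternatives, no 1/f
  parameterization, no TFCE or FDR alternatives to cluster inference.
* Real-data ingestion assumes cleaned, source-level time series; the
  optional `preprocess_signals()` (zero-phase FIR high-pass at 1 Hz plus
  anti-aliased downsampling) covers drift removal and rate matching, not
  artifact rejection or source reconstruction.
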