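---
title: "Modelling the zero-TE fMRI impulse response and its coupling to neuronal activity"
author: "ztefmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the zero-TE fMRI impulse response and its coupling to neuronal activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ztefmri)
```

## The scientific problem

Zero echo time (zero-TE) pulse sequences such as MB-SWIFT sample free
induction decays during very fast radial readouts, which makes the
acquisition quiet, motion-tolerant and nearly immune to susceptibility
artifacts — but also insensitive to the T2/T2\*-dependent BOLD effect.
The functional contrast is instead attributed to inflow/volume
(CBF/CBV-like) hemodynamics.  Two questions follow for anyone who wants
to use zero-TE fMRI quantitatively:

1. What impulse response function (IRF) links neuronal activity to the
   zero-TE signal, and how do its onset time (OT), time-to-peak (TTP)
   and full-width-at-half-maximum (FWHM) compare to known hemodynamic
   kernels?
2. How well does IRF-convolved electrophysiology predict the zero-TE
   response across stimulation frequencies, and where does the linear
   model break down?

This package implements the complete analysis chain for simultaneous
epidural iEEG + zero-TE fMRI experiments in rat somatosensory cortex
under whisker stimulation, together with a synthetic-data generator
that stands in for raw recordings, which are not publicly deposited.

## The IRF model

The hemodynamic kernel is a gamma probability density with an explicit
onset delay,

$$
f(x) \;=\;
\begin{cases}
\dfrac{(x-\tau)^{\alpha-1}\,\beta^{\alpha}\,
e^{-\beta (x-\tau)}}{\Gamma(\alpha)}, & x \ge \tau\\[4pt]
0, & x < \tau
\end{cases}
$$

with shape $\alpha > 0$, rate $\beta > 0$ (1/s) and onset $\tau \ge 0$
(s).  Because the density integrates to one, convolution preserves the
area of the neuronal input and the amplitude scale can be carried by a
single regression coefficient.  One numerical convention is worth
noting: for $\alpha < 1$ the density diverges at $x = \tau$; on a
sampling grid that point carries no mass and `gamma_irf()` evaluates it
as zero.

`characterize_irf()` reports OT, TTP and FWHM numerically: OT is the
earliest time with $f > 0$ refined by bisection, TTP is located on a
fine bracketing grid and polished by local optimisation, and the FWHM
crossings are found by bisection to $10^{-6}$ s.  All three are rounded
to a reporting precision of 0.1 s.  At the derived parameters
$(\alpha, \beta, \tau) = (2.9, 1.2, 0.5)$:

```{r}
characterize_irf(function(t) gamma_irf(irf_params(2.9, 1.2, 0.5), t))
```

The double-gamma BOLD kernel of Lambers and colleagues
(`lambers_double_gamma()`, with its undershoot term) is provided as a
literature reference; its TTP of 3.1 s illustrates the delay of BOLD
relative to the faster CBV/CBF-like zero-TE response.  A gamma-variate
model attributed to Martindale and colleagues is included only as a
clearly flagged literal transcription (`martindale_gamma_variate()`);
the printed formula is typographically ambiguous, the transcription
does not reproduce the published peak times, and no analysis in this
package uses it.

## The grid-search convolution fit

`fit_irf_grid()` defines the estimator.  For every triple on the search
grid — by default shape $0.1, 0.2, \ldots, 15$, rate $0.1, \ldots, 15$
per second and onset $0, 0.1, \ldots, 1$ s, built from integers scaled
by ten so the printed decimals are exact — the mean baseline-corrected
neuronal power epoch is convolved with the kernel at the power series'
own rate, bin-averaged to the fMRI resolution (100-ms bins for the
event-related design), scaled by a single least-squares amplitude
factor, and compared with the mean baseline-corrected fMRI epoch by the
sum of squared residuals (SSR).  The winner is the triple with the
smallest SSR, ties broken lexicographically by (shape, rate, onset).

Numerical design choices:

* **No intercept.** Both epochs are baseline-corrected against their
  pre-stimulus windows, so the amplitude factor is the only free
  scalar.  This matches the no-intercept convention used in the
  time-course regressions.  Consequently $R^2 = 1 - \mathrm{SSR} /
  \sum y^2$ (total sum of squares about zero), which is the quantity
  bounded by 0 and 1 for this estimator.
* **Kernel truncation.** Inside the fit the kernel is truncated at the
  epoch length; this is exact for the fitted window because output
  samples inside the epoch never see kernel mass from beyond it.  The
  standalone `convolve_power_with_irf()` defaults to a 60-s span and
  refuses truncations whose tail mass exceeds `tail_tol`, reporting
  the span that would suffice.
* **Vectorised evaluation.** The binned convolution is a linear map of
  the kernel samples, so the fit precomputes a single
  (kernel-length × bin-count) operator from the power epoch and sweeps
  the whole grid with matrix products, looping over shape values to
  bound memory.  An independent naive route (convolve, then
  `downsample_bins()`, then scale) is kept in the test suite as a
  brute-force oracle; the two agree to within floating error.
* **Convolution rate.** The derivation pipeline down-samples the mean
  power epoch to 100 Hz before the fit.  The IRF at physiological
  parameters has negligible content above a few hertz, so this changes
  the binned predictions at the $10^{-4}$ relative level while cutting
  the grid sweep cost by orders of magnitude; exact on-grid parameter
  recovery is unaffected.

## The iEEG path

Conditioning follows the standard chain: MRI gradient-artifact template
subtraction (block design only), band-pass, notch filtering, electrode
selection, squaring, epoching and baseline correction.

* The **artifact template** is the average of the signal over the first
  90 volume-trigger-locked windows of the stimulus-free baseline;
  averaging attenuates uncorrelated signal by $1/\sqrt{90}$ while the
  volume-locked artifact survives.  Subtraction at every trigger is
  exact (machine precision) for a perfectly repeating artifact, which
  is how the generator builds it.  Trailing partial windows are
  skipped with a warning.
* The **band-pass** (4–190 Hz) is realised as a cascade of 4th-order
  Butterworth high- and low-pass sections rather than a single
  band-pass prototype: at 4 Hz against a 5-kHz rate a combined
  band-pass transfer function is numerically fragile, while the
  cascade is stable and has the same nominal order.  The **notches**
  (50/100/150 Hz) are standard constrained biquads with Q = 30, about
  −97 dB at the line frequency after forward–backward application.
  Every stage runs forward–backward with odd-reflection padding, so
  filtering is zero-phase and response timing is preserved.
* **Electrode selection** picks the candidate with the highest ratio of
  mean power during stimulation to mean power over the whole
  recording; ties go to the lowest index.  The stimulation windows are
  the nominal `[onset, onset + duration)` intervals.
* **Epoch alignment** uses the recording's own sample grid: the first
  sample of an epoch is the first grid point at or after
  `onset + rel_start`, and windows are half-open.  No resampling takes
  place.  Events whose pre-stimulus window precedes the start of the
  recording (the first event of the event-related design can start
  within 2 s of acquisition onset) are dropped from averaging with a
  warning.
* **Squaring** maps the filtered voltage to instantaneous power
  (mV²); no smoothing is applied between squaring and convolution.

## The fMRI path

* **Detrending** uses a zero-phase 2nd-order Butterworth high-pass at
  1/100 Hz with reflection padding.  A moving-average baseline with
  window equal to the cutoff was considered and rejected: its comb-like
  response leaves components with periods between one and three times
  the window almost untouched (the Dirichlet kernel has a null exactly
  at the window length), so a 300-s scanner drift would survive nearly
  intact.  The Butterworth realisation suppresses a 300-s drift by
  about 99% while passing 10-s-period signal within 5%.  Note that any
  100-s high-pass mildly distorts a 60-s-cycle block design itself
  (the fundamental loses about 11%); this is a property of the
  analysis choice, shared with the original pipeline, and its main
  visible effect is a few-percent leakage between neighbouring block
  responses.
* **ROI extraction** averages mask voxels per volume from 4-D NIfTI
  (via RNifti), with an optional left–right flip for experiments in
  which the stimulated side was mirrored.
* **Event-reordered rebinning** models the temporal-resolution
  enhancement of the radial acquisition at the time-course level: each
  spoke (one ~1-ms radial readout) is assigned to a peristimulus bin
  by `floor((t_rel - rel_start)/bin_s)` over half-open bins, pooling
  spokes across the 20 jittered events.  The default 14-s window at
  0.1-s bins yields exactly 140 bins with on the order of 2000 spokes
  each.  Image reconstruction itself (re-gridding, iterative
  reconstruction) is out of scope; a per-spoke surrogate signal is
  rebinned instead, which reproduces the combinatorics and the
  resolution-enhancement property.

## The coupling analysis

Response size is the sum of time-course values over a half-open window
on the 2-s bin grid: the "22-s window" is 11 bins, the "first 4 s" 2
bins.  Sizes are z-scored within experiment (sample standard deviation,
$n-1$), then averaged over all trials per subject and frequency; the
response-size regressions (`linear_fit()`, ordinary least squares) are
computed with intercept, over all frequencies and over the 1–7 Hz
subset, for both windows.  MSE is defined as SSR/$n$.  Time-course
comparisons use the "mean of means" convention — trials averaged
within subject first, subjects averaged second, so subjects with
different trial counts weigh equally — and per-frequency no-intercept
fits; `fixed_scaling_residuals()` instead fixes one global coefficient
on the first 4 s of the 7-Hz response (the condition closest to the one
the IRF was derived under) and reports the residual time courses at
every frequency.

## What the synthetic generator emulates

The generator produces the two study designs with their published
geometry: the event-related design (20 × 1-s 7-Hz trains, 48-s cycles,
16 min, onsets jittered over a deterministic grid so peristimulus
phases tile the sub-volume interval) and the block design (180-s
baseline + 28 × [16-s block + 44-s rest] = 31 min, seven frequencies
of 1–17 Hz in seed-randomised order, 930 2-s volumes).

* **Evoked waveform.** Each stimulus pulse evokes a triphasic
  waveform — positive, larger negative, slower positive — realised as
  three Gaussian lobes spanning less than 143 ms (one 7-Hz
  inter-pulse interval), with default amplitudes 0.2/−0.5/0.1 mV.
  Within a train the $k$-th response is scaled by
  $a(k) = a_\infty + (1-a_\infty)e^{-(k-1)/\kappa(f)}$ with floor
  $a_\infty = 0.4$ and $\kappa(f) = 20/\sqrt{f}$ pulses.  The rate
  constant decreases with frequency while the corresponding time
  constants $\kappa/f$ fall from roughly 20 s at 1 Hz to a third of a
  second at 17 Hz — adaptation is faster and more complete at high
  rates, and at low rates it evolves over seconds, which is what makes
  the "first 4 s" of a block a meaningfully less-adapted epoch.
* **Contamination.** Broadband Gaussian noise (0.02 mV), power-line
  sinusoids at 50/100/150 Hz with seed-drawn phases, and a
  deterministic gradient-artifact burst repeated exactly at every
  volume trigger.  Exact repetition is deliberate: it makes template
  subtraction exactly correct, isolating the estimator's averaging
  error in tests.
* **fMRI forward model.** The clean neuronal power is convolved with
  the ground-truth IRF (default $(2.9, 1.2, 0.5)$), scaled by a gain
  of 50 — chosen so a single-block response peaks at roughly ten times
  the per-bin noise (sd 0.025), a mid-range contrast-to-noise for a
  high-field block design — bin-averaged to the acquisition
  resolution, and contaminated with a slow sinusoidal drift (period
  300 s, above the 100-s high-pass cutoff so the detrending stage is
  exercised) plus Gaussian noise.
* **Planted nonlinearities (block design).** Two stimulation-dependent
  residual components decouple the fMRI response from the linear
  prediction, mirroring the phenomena the analysis is designed to
  expose: a per-frequency gain profile ($1 + 0.04\,(f - 7)$, so the
  apparent neurovascular gain grows with stimulation frequency), and a
  slow session-scale drift of the coupling gain that applies only
  after the first 4 s of each block (amplitude 0.8, period 600 s).
  The late drift leaves the first 4 s faithfully coupled while partly
  decoupling the sustained response, so regressions restricted to the
  early window fit better than full-window regressions — the
  qualitative signature the windowed analysis is meant to detect.  A
  time-invariant late gain was tried first and rejected: a distortion
  that is monotone across frequencies is absorbed almost entirely by a
  with-intercept regression on standardized sizes and leaves the
  full-window fit spuriously clean.
* **Reproducibility.** All randomness flows through one seeded
  generator per call; the global RNG state of the session is saved and
  restored, and identical configurations give bit-identical datasets.

What the generator does **not** emulate: spatial structure (a single
ROI time course stands in for the image series, except for a small
NIfTI phantom used to exercise ROI extraction), physiological noise
spectra (cardiac/respiratory), non-repeating gradient artifacts,
electrode drift, and any true nonlinear hemodynamic model — the
planted residuals are descriptive, not mechanistic.  Passing tests on
synthetic data therefore validate the estimators and the pipeline
plumbing, not the physiological claims.

## Problem sizes and runtimes

The test suite simulates iEEG at 1 kHz (comfortably above twice the
190-Hz band edge and the waveform content) and uses three synthetic
subjects with four blocks per frequency for the coupling checks; the
full 150 × 150 × 11 grid search runs once on a noise-free
event-related dataset, and the acceptance script repeats it at the
full 5-kHz recording rate.  On one CPU the full grid sweep takes on
the order of one to a few minutes; the coarse 15 × 15 × 11 smoke grid
runs in seconds.

## Known limitations

* The grid-search ridge: neighbouring triples such as
  $(2.6, 1.1, 0.6)$ and $(3.2, 1.3, 0.4)$ produce nearly
  indistinguishable convolutions of a 1-s stimulus response, so
  single-trial-level noise on the *mean* epoch quickly spreads the
  argmin along this ridge.  Averaging across the 20 events (as the
  derivation does) is what makes exact recovery robust.
* The event-reordered scheduler works on per-spoke surrogate values;
  no claim is made about the actual modified spoke trajectory of the
  acquisition, which is treated purely as a stream of timestamps.
* The 100-s high-pass inevitably interacts with the 60-s block cycle
  (see above); response sizes computed from very few bins inherit a
  few-percent systematic wobble from it even without noise.
* The coupling analysis deliberately stops at descriptive regressions;
  no mixed-effects modelling of subject variance and no nonlinear
  convolution models are provided.
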