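---
title: "Methods: simulated flower echoes, target strength, and echo-based classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated flower echoes, target strength, and echo-based classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floralecho)
```

`floralecho` studies a sensory-ecology question: do flowers pollinated by
echolocating bats differ acoustically from flowers pollinated by insects or
birds, and can species be recognised from their ultrasonic echoes alone?
The package provides a fully synthetic but statistically calibrated version
of such a study — a generator for flower specimens and their impulse
responses, the sonar signal-processing chain, the morphological and
statistical comparisons, and a convolutional classifier for echo
spectrograms — so that every stage can be tested end to end without any
recordings.

This vignette documents the models, the tunable parameters, the numerical
conventions, and the design decisions taken where more than one reasonable
choice existed. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The measurement model

A flower is mounted 20 cm from a sonar head and rotated from −90° to +90°
in 1.8° steps (101 angles per plane), in an azimuth and an elevation plane,
giving 202 echoes per flower. The excitation is a maximum length sequence
(MLS): a ±1 pseudorandom sequence of length $2^m-1$ whose circular
autocorrelation is $L$ at lag zero and $-1$ elsewhere. We use order
$m = 14$ (16383 samples), played periodically at 500 kHz, so one period
lasts ≈ 33 ms.

`deconvolve()` recovers the impulse response by slicing the recording into
whole periods, averaging, and circularly cross-correlating with the MLS via
FFT (normalised by $L$). Conventions worth stating:

* A 2 s recording holds 61 whole periods. The first period is treated as
  the transient of the periodic convolution and discarded, leaving 60
  usable periods, of which the first 50 (periods 2–51) are averaged.
  `mls_period_count()` reports both counts; both are configurable.
* Averaging $m$ periods reduces residual noise power by $10\log_{10} m$
  (≈ 17 dB for 50), which the test suite verifies by Monte Carlo.
* The cross-correlation estimator carries an $O(1/L)$ bias (the MLS
  autocorrelation is $-1$, not $0$, off-peak); at $L = 16383$ this is
  negligible against measurement noise and is left uncorrected.

`extract_echo()` cuts the flower echo out of the impulse response with a
rectangular 1024-sample window. The peak search skips a configurable guard
interval (default 0.8 ms) standing in for direct transmitter–receiver
crosstalk; at the 20 cm geometry the echo arrives at ≈ 1.17 ms, safely
beyond it. The window starts 128 samples before the detected peak, keeping
leading-edge energy. Echo detection requires the peak to exceed 5× a robust
noise estimate (the MAD of a 1-in-7 decimated sample of the search region —
decimation is purely an economy; the estimate is still over hundreds of
samples); otherwise the function signals "no echo found".

`power_spectrum()` is the one-sided magnitude-squared FFT, scaled so total
spectral power equals total sample energy (Parseval). `calibrate_ts()`
subtracts (in dB) the spectrum of a reference-plate measurement processed
through the identical chain; any transmit/receive coloration common to both
cancels exactly, which is the point of plate calibration. The result is a
spectral target strength (TS) referenced to the plate at 10 cm; that
reference distance is metadata only — no spreading-loss renormalisation is
applied beyond the plate difference.

All aggregation of TS values — across frequency bins within a band, across
the 101 angles of a plane, and across the two planes — averages on the
linear power scale and converts back to dB ("delog" averaging). The source
convention only states delog averaging for the band step; applying it
throughout is a deliberate, uniform choice, flagged here as an assumption.
Band membership is by bin centre in the closed interval
$[f_{low}, f_{high}]$. The default bands are the broad 40–160 kHz band and
45, 68, 102 and 153 kHz, each ±20%.

## The synthetic-data generator

### Flowers

`make_catalog()` returns twelve species in six families, one bat-pollinated
and one insect- or bird-pollinated species per family. The species names
follow the classic chiropterophily literature; their mean morphological
features are synthetic calibration values (the package ships no measured
morphology). They were chosen once so that (a) surface areas span a factor
of ≈ 22 (270–7400 mm²), making the log-linear regression identifiable, and
(b) both syndromes cover the size range, keeping the syndrome/size
correlation — and hence the bias it induces in the area-only regression
slope — small (about +0.2 dB per ln mm², ~6% of the slope).

Relative variability is the biologically meaningful dial: bat-pollinated
flowers are morphologically conserved. Defaults are `cv_target` 0.08 (bat)
and 0.16 (other), with a ±20% uniform per-species jitter so species differ
within a syndrome. `sample_flowers()` draws each feature as
$\mu(1 + c_V z)$, $z \sim N(0,1)$, redrawing non-positive values (at most
100 attempts). Surface area is always recomputed from the drawn features,
never stored independently.

### Acoustics

`acoustic_truth()` holds the planted flower-level model

$$TS = a\,\ln F_{sur} + b + \Delta\cdot[\text{bat}] + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma^2),$$

with defaults $a = 3.488$ dB per ln mm², $b = -32.422$ dB, $\Delta = +3$ dB
and $\sigma = 1.2$ dB. The slope and intercept are the calibration targets
the analysis is expected to recover; $\Delta$ is of the order of the
residual separation between syndromes the analysis should detect, and
$\sigma$ was set from the variance decomposition so that the area-only
regression attains $R^2 \approx 0.8$ on the default catalog (the planted
syndrome offset itself contributes residual variance to that regression).

`simulate_impulse_response()` is a deliberately minimal physical stand-in,
not a claim about real flowers: each echo is two discrete reflections — the
corolla rim at the target range, and the interior wall delayed by the round
trip across the *projected* corolla depth, $2 d \cos\theta / c$. Two paths
produce an interference comb with notch spacing $c/2d$ head-on, so larger
(deeper) bells show more notches in a fixed band, and the projection makes
the notch frequencies migrate with the angle of incidence, producing the
"spotted" directional spectra characteristic of bell flowers. (A fixed,
unprojected delay was considered and rejected: it cannot move the notches
across angles.) The amplitude envelope follows a smooth
$\exp(\kappa\cos\theta)$ directivity, normalised over the scan grid so the
angle-averaged power equals the planted flower-level TS exactly; the
interior/rim amplitude ratio falls off as $\cos^2\theta$ from 0.9 head-on
to zero side-on. Zero depth degenerates to a single reflection. What this
model does *not* emulate: petal texture, wax-layer impedance, multiple
scattering, frequency-dependent absorption — so classifier results on
synthetic data demonstrate that the pipeline can exploit shape-driven
spectral structure, not that real flowers are equally separable.

`simulate_recording()` convolves the periodically repeated MLS with an
impulse response and adds white Gaussian noise at a stated SNR.
`synthesize_call()` produces a glossophagine-like call: 1.5 ms downward
hyperbolic FM sweep, fundamental 80 → 45 kHz with a second harmonic,
Hann-tapered; the parameters are documented package constants (no measured
call is shipped).

## Morphometrics

The reflective surface of a bell-shaped corolla is modelled as a paraboloid
chalice plus the corolla-opening disc:

$$F_{sur} = \frac{\pi r_p}{6h^2}\left[(r_p^2+4h^2)^{3/2}-r_p^3\right] +
\pi r_c^2,$$

with $r_p$ half the mean inner diameter, $r_c$ half the mean outer
diameter, and $h$ the corolla length; mean diameters are the arithmetic
mean of the horizontal and vertical measurements. As $h \to 0$ the bracket
degenerates numerically; the analytic limit $\pi r_p^2$ is substituted for
very flat chalices. The paraboloid term is verified against numerical
quadrature of the lateral surface in the test suite.

The coefficient of variation uses the sample ($n-1$) standard deviation —
the denominator convention is not dictated by the formula $c_V=\sigma/\mu$
itself, so the package fixes the sample version. Features entirely missing
for a species are skipped, not zero-filled; species with fewer than two
flowers are dropped with a warning. Alternative measurement protocols for
morphologically atypical species (petal-based measurements, absent calyx)
are supported as optional columns but excluded from the default
cross-species feature set.

## Statistics

* `fit_ts_regression()` is OLS of band TS on $\ln F_{sur}$ (natural log,
  as the model notation implies), returning a classed object with
  `print`/`summary`/`coef`/`predict`/`residuals`/`plot` methods.
* `residual_syndrome_test()` is a Welch (unequal-variance) two-sample
  *t*-test on the residuals; Welch is the variant with fractional degrees
  of freedom, matching the reporting convention of such comparisons.
* `acoustic_cv_table()` computes the per-species cV of band TS on the
  linear-power scale. A cV of dB values would depend on the arbitrary 0 dB
  reference (a species with TS near plate level would get an unbounded
  cV); on the linear scale TS is a positive intensity ratio and
  $c_V \approx \frac{\ln 10}{10}\,\mathrm{sd}_{dB}$ for small spreads, so
  orderings agree wherever both are defined.
* `lmm_compare()` performs likelihood-ratio comparisons of nested linear
  mixed models with a random intercept for plant family, refit by maximum
  likelihood (REML likelihoods of models with different fixed effects are
  not comparable). The $\chi^2$ reference is slightly conservative when
  the family variance is estimated near zero (a boundary effect); this is
  documented rather than corrected. No multiple-testing correction is
  applied anywhere.

## The echo classifier

Echoes are synthesised on demand by convolving the impulse response with
the call, high-pass filtered at 5 kHz (4th-order Butterworth, zero-phase)
to remove low-frequency leakage, and trimmed/padded to a fixed length.
Spectrograms use a 256-sample Hann window with a hop of 26 samples — 90%
overlap rounds 25.6 to 26; the hop is configurable — converted to dB with
an −80 dB floor and min–max normalised per spectrogram. Normalisation
deliberately discards absolute echo level: the classifier sees spectral
shape, not loudness.

The network takes $k \in \{1,3,5,7,10\}$ spectrograms simultaneously. Each
passes through a shared branch — conv(16 channels, 3×3, stride 1), ReLU,
max-pool(3×3, stride 2) — with identical weights for every input, so the
branch parameter count is independent of $k$. The branch outputs are
concatenated along channels and processed by conv(32, 3×3), ReLU,
max-pool(3×3, stride 2), then three dense layers (256, 128, then the
12-way softmax; widths are package defaults, as are ReLU activations and
the dB floor — none of these is externally prescribed). Training uses
cross-entropy, Adam at learning rate $10^{-4}$, batch size 16, shuffled
training batches and an unshuffled validation pass, with early stopping on
validation loss at a patience of 8 epochs (the patience value is a package
default) and restoration of the best-validation parameters. Convolution
and pooling (forward and backward) run in compiled code; gradients are
verified against finite differences in the test suite.

Two chunking schemes emulate a bat's approach. *Random*: a flower's 202
echoes (both planes pooled) are shuffled and partitioned into groups of
$k$, remainder dropped. *Interval*: a random stride $n \in \{2,\dots,8\}$
and start angle are drawn and every $n$th echo taken within one plane's
angular order, no wrap-around, redrawing if the run leaves the scan — the
contiguous-trajectory reading of echoes "coming in succession from one
direction"; chunk counts are matched to the random scheme for fairness.
Interval chunks are measurably less angularly diverse (the package exposes
`chunk_angle_spread()` for exactly this check). Note the contrast between
schemes requires the fine 1.8° grid: with coarse grids even stride-8 runs
span a wide angular sector and the schemes converge.

Splitting is stratified per individual flower — 8 train, 2 validation,
2 test flowers per species by default, leftovers unused — so no flower
contributes echoes to two subsets. (The stated-counts reading of 8/2/2 of
14 flowers is used; the alternative "58%/21%/21%" phrasing is inconsistent
with those counts, and the counts win. Both are configurable.) Per-syndrome
accuracies carry 95% Clopper–Pearson binomial intervals.

## Problem sizes and determinism

The test suite and acceptance script choose sizes that keep a full run on
one CPU comfortable while preserving every qualitative contrast:

* Regression and cV recovery run the full study geometry (168 flowers,
  101 angles × 2 planes, 1024-sample windows); the acceptance script
  averages the recovered slope over 200 replicates and the cV means over
  50 seeds. The test suite uses 25 replicates for the same check.
* The record → deconvolve → calibrate oracle runs one full 2 s, 500 kHz
  recording at 40 dB SNR against the analytic two-path transfer function.
* The classifier study uses 3 well-separated species (corolla depths 40,
  16 and 6 mm), 12 flowers each, the full 101-angle grid, 768-sample
  echoes, and a per-flower cap of 12 chunks (24 for the headline accuracy
  run) — a deliberately small but honest version of the 12-class problem.
  Its assertions are statistical orderings with explicit tolerances of
  about one confidence-interval half-width.

All stochastic stages take explicit integer seeds; identical seeds give
bit-identical catalogs, flowers, impulse responses and recordings. CNN
training is reproducible in single-threaded BLAS; with threaded BLAS,
floating-point summation order can perturb trajectories, so cross-machine
agreement of trained-model accuracies is statistical rather than exact.

## Known limitations

* The impulse-response model is two discrete reflections; real corollas
  produce distributed, rough returns. Absolute TS levels and classifier
  accuracies on synthetic data therefore do not transfer to recordings.
* A cV target accurate at the feature level slightly understates the cV of
  derived quantities such as surface area (a nonlinear function of several
  features); the per-syndrome contrast is unaffected.
* The total echo count of a real campaign depends on how many flowers are
  scanned in one plane only; the generator documents its own count
  (202 × flowers) rather than forcing any particular published total.
* The mixed-model stage delegates fitting to `lme4`; convergence failures
  are raised as errors, never silently ignored.
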