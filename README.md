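# floralecho

Echo-acoustic analysis of flowers across pollination syndromes, and
species classification from ultrasonic echoes.

Nectar-feeding bats find their flowers in the dark by echolocation, and
several chiropterophilous plants have evolved acoustically conspicuous
floral parts. `floralecho` implements the complete computational chain used
to ask how bat-pollinated flowers differ acoustically from insect- and
bird-pollinated ones:

* **Synthetic study generator** — species catalogs (six families, one
  bat-pollinated and one otherwise-pollinated species each), individual
  flowers with syndrome-specific morphological variability, angle-indexed
  two-path impulse responses whose broadband target strength follows a
  calibrated log-linear law in flower surface area, raw
  maximum-length-sequence (MLS) ensonification recordings, and a synthetic
  multi-harmonic frequency-modulated bat call.
* **Sonar processing** — MLS generation (order 14, 16383 samples at
  500 kHz), impulse-response recovery by period-averaged FFT
  cross-correlation, 1024-sample echo windowing, power spectral density,
  calibration against a reference-plate measurement to spectral target
  strength (TS, dB re plate at 10 cm), and "delog" (linear-power) averaging
  over frequency bands (40–160 kHz broad band; 45, 68, 102, 153 kHz ± 20 %),
  angles (−90°…+90° in 1.8° steps, 101 per plane) and the two scan planes.
* **Morphometrics** — bell-flower surface area as a paraboloid chalice plus
  the corolla-opening disc,

      F_sur = (pi * r_p / (6 h^2)) * ((r_p^2 + 4 h^2)^(3/2) - r_p^3) + pi * r_c^2

  and coefficients of variation c_V = sigma / mu per species and feature.
* **Statistics** — OLS regression `TS = a ln(F_sur) + b`, Welch *t*-test of
  the regression residuals by pollination syndrome, per-syndrome c_V
  summaries (morphological and acoustic), and likelihood-ratio comparisons
  of nested linear mixed models with plant family as a random intercept.
* **Echo classifier** — a multi-input convolutional network: k echo
  spectrograms (Hann 256, 90 % overlap) pass through a shared conv(16,
  3×3)/max-pool(3×3, stride 2) branch, are concatenated, and continue
  through conv(32)/pool and three dense layers to a 12-way softmax; trained
  with Adam (learning rate 1e-4, batch 16), cross-entropy and early
  stopping, with chunking schemes emulating a bat's approach (random angles
  vs. interval runs) and a strict per-flower train/validation/test split.

## Worked example

```r
library(floralecho)

truth <- acoustic_truth()           # TS = 3.488 ln(area) - 32.422 + 3*[bat]
fl    <- sample_flowers(make_catalog(seed = 1), n_per_species = 14, seed = 2)
tab   <- flower_ts_table(fl, truth, sim_config(seed = 3))

fit <- fit_ts_regression(tab)
print(fit)
#> Target strength ~ ln(surface area) [ts_broad]
#>   TS = 3.668 ln(area) -32.232 dB
#>   R^2 = 0.802, F(1, 166) = 672.9, n = 168

print(residual_syndrome_test(fit))
#> Welch t-test of TS residuals by pollination syndrome
#>   mean residual: bat +1.46 dB, other -1.46 dB (diff +2.93)
#>   t = 16.224, df = 162.68, p = 7.98e-36
```

168 simulated flowers recover the planted log-linear slope (3.668 vs. the
configured 3.488, within sampling error), the planted R² ≈ 0.8, and the
planted +3 dB syndrome offset in the residuals (+2.93 dB). The same objects
feed the variability comparison (`species_cv_table`, `cv_syndrome_summary`)
and, via `scan_set` / `train_echonet` / `evaluate_echonet`, the classifier.

A command-line front end for processing scan containers and training the
classifier is installed at `inst/cli/floralecho.R`.

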