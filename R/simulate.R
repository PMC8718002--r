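#' Simulate one impulse response of a flower
#'
#' Physically motivated stand-in for a measured flower impulse response: a
#' two-path reflector with a rim reflection at the target range and an
#' interior-wall reflection delayed by the round trip across the projected
#' corolla depth, `2 * depth * cos(angle) / c` (head-on the full depth is
#' traversed). The superposition of the two paths produces the
#' interference comb seen in bell-shaped flowers, with notches spaced
#' `c / (2 depth)` in frequency - so larger (deeper) flowers show more
#' interference notches in a fixed band. Relative amplitudes vary smoothly
#' with angle (see [acoustic_truth()]) and the overall scale is set so the
#' recovered broadband target strength, averaged over angles and planes,
#' matches `ts_db`. A zero depth degenerates to a single reflection (no
#' comb).
#'
#' @param flower one-row flower data frame (needs `inner_depth` in mm).
#' @param angle angle of sound incidence in degrees (must lie on the grid).
#' @param plane `"azimuth"` or `"elevation"` (metadata only; the synthetic
#'   reflector is rotationally symmetric).
#' @param truth an [acoustic_truth()].
#' @param cfg a [sim_config()].
#' @param ts_db flower-level broadband target strength in dB; defaults to the
#'   noise-free [expected_ts()] of the flower.
#' @return numeric impulse response of length `cfg$ir_length`.
#' @export
simulate_impulse_response <- function(flower, angle,
                                      plane = c("azimuth", "elevation"),
                                      truth = acoustic_truth(),
                                      cfg = sim_config(),
                                      ts_db = expected_ts(flower, truth)) {
  plane <- match.arg(plane)
  angles <- sim_angles(cfg)
  if (min(abs(angles - angle)) > 1e-9)
    stopf("angle %g is not on the scan grid", angle)
  .scan_ir_matrix(flower, angles = angle, truth = truth, cfg = cfg,
                  ts_db = ts_db)[1, ]
}

# Core generator: IR matrix (n_angles x ir_length) for one flower.
# Per-angle total echo power = flower power * directivity weight; split
# between the rim spike and the interior spike with angle-dependent ratio.
.scan_ir_matrix <- function(flower, angles, truth, cfg, ts_db) {
  fs <- cfg$sample_rate
  d0 <- round(2 * cfg$target_distance / cfg$speed_of_sound * fs)
  depth_m <- flower$inner_depth / 1000
  # path difference projects with the angle of incidence: head-on the full
  # corolla depth is traversed twice, side-on the two paths coincide -- this
  # makes the notch frequencies shift across angles ("spotted" pattern)
  tau <- round(2 * depth_m * cos(angles * pi / 180) /
               cfg$speed_of_sound * fs)
  if (d0 + max(tau) + 1 > cfg$ir_length)
    stopf("ir_length %d too short for delay %d + %d", cfg$ir_length, d0,
          max(tau))
  # weights normalised over the full grid, then subset, so single-angle calls
  # are consistent with full scans
  full <- sim_angles(cfg)
  w_full <- .angle_weights(full, truth$angle_kappa)
  w <- w_full[match(round(angles, 9), round(full, 9))]
  r <- .path_ratio(angles, truth$two_path_ratio)
  p <- db_to_power(ts_db) * w          # per-angle total linear power
  a1 <- sqrt(p / (1 + r^2))
  a2 <- r * a1
  ir <- matrix(0, nrow = length(angles), ncol = cfg$ir_length)
  ir[, d0 + 1] <- a1
  two <- tau > 0
  if (any(two)) {
    sel <- cbind(which(two), d0 + 1 + tau[two])
    ir[sel] <- ir[sel] + a2[two]
  }
  if (any(!two)) ir[!two, d0 + 1] <- ir[!two, d0 + 1] + a2[!two]
  ir
}

#' Simulate a full scan of a flower in one plane
#'
#' 101 (by default) impulse responses over the angle grid, the simulated
#' analogue of rotating a flower in front of the sonar head.
#'
#' @inheritParams simulate_impulse_response
#' @return object of class `ir_scan`: list with `flower_id`, `species`,
#'   `syndrome`, `family`, `plane`, `angles`, `sample_rate` and `irs`
#'   (matrix n_angles x ir_length).
#' @export
simulate_scan <- function(flower, plane = c("azimuth", "elevation"),
                          truth = acoustic_truth(), cfg = sim_config(),
                          ts_db = expected_ts(flower, truth)) {
  plane <- match.arg(plane)
  angles <- sim_angles(cfg)
  irs <- .scan_ir_matrix(flower, angles, truth, cfg, ts_db)
  structure(list(flower_id = flower$flower_id, species = flower$species,
                 syndrome = flower$syndrome, family = flower$family,
                 plane = plane, angles = angles,
                 sample_rate = cfg$sample_rate, irs = irs),
            class = "ir_scan")
}

#' @export
print.ir_scan <- function(x, ...) {
  cat(sprintf("IR scan: flower %s (%s), %s plane, %d angles x %d samples\n",
              x$flower_id, x$species, x$plane, nrow(x$irs), ncol(x$irs)))
  invisible(x)
}

#' Reference-plate impulse response
#'
#' The calibration reference: an ideal unit reflector at the target range.
#' Real plate recordings are processed through the identical chain.
#'
#' @param cfg a [sim_config()].
#' @return numeric impulse response of length `cfg$ir_length`.
#' @export
plate_impulse_response <- function(cfg = sim_config()) {
  d0 <- round(2 * cfg$target_distance / cfg$speed_of_sound *
              cfg$sample_rate)
  ir <- numeric(cfg$ir_length)
  ir[d0 + 1] <- 1
  ir
}

#' Simulate a raw MLS ensonification recording
#'
#' Convolves a periodically repeated MLS with an impulse response and adds
#' white Gaussian noise at the requested SNR (signal power relative to noise
#' power). With a unit-impulse IR and infinite SNR the steady-state recording
#' is the periodic MLS itself.
#'
#' @param ir impulse response (must not exceed one MLS period).
#' @param mls an [generate_mls()] object.
#' @param duration_s recording duration in seconds (must cover at least two
#'   MLS periods).
#' @param snr_db signal-to-noise ratio in dB; `Inf` for noise free.
#' @param seed integer seed for the noise.
#' @return numeric vector of `duration_s * sample_rate` samples.
#' @export
simulate_recording <- function(ir, mls, duration_s = 2.0, snr_db = Inf,
                               seed = NULL) {
  L <- length(mls$values)
  if (length(ir) > L) stopf("IR (%d) longer than one MLS period (%d)",
                            length(ir), L)
  n <- round(duration_s * mls$sample_rate)
  if (n < 2 * L) stopf("duration must cover at least two MLS periods")
  n_per <- ceiling(n / L) + 1
  x <- rep(mls$values, n_per)
  rec <- .fft_convolve(x, ir)[seq_len(n)]
  if (is.finite(snr_db)) {
    sigma <- sqrt(mean(rec^2)) * 10^(-snr_db / 20)
    rec <- rec + with_seed(seed, rnorm(n, sd = sigma))
  }
  rec
}

# linear convolution via FFT, length(x) + length(h) - 1 truncated to x
.fft_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1
  nfft <- 2^ceiling(log2(n))
  X <- fft(c(x, numeric(nfft - length(x))))
  H <- fft(c(h, numeric(nfft - length(h))))
  Re(fft(X * H, inverse = TRUE))[seq_len(n)] / nfft
}

#' Synthesize a nectar-feeding-bat echolocation call
#'
#' A short downward hyperbolic FM sweep with two harmonics, Hann
#' amplitude-tapered: a glossophagine-like broadband call covering roughly
#' 40-160 kHz. All parameters are exposed; the defaults are documented
#' package constants, not measured values.
#'
#' @param cfg a [sim_config()] (supplies the sampling rate).
#' @param duration_s call duration in seconds.
#' @param f_start,f_end start and end frequency of the fundamental in Hz
#'   (downward sweep; the second harmonic spans twice these).
#' @param harmonics number of harmonics (>= 1).
#' @param harmonic_weights relative amplitude per harmonic.
#' @return numeric waveform with attributes `sample_rate` and
#'   `instantaneous_frequency` (fundamental, Hz per sample).
#' @export
synthesize_call <- function(cfg = sim_config(), duration_s = 1.5e-3,
                            f_start = 80e3, f_end = 45e3, harmonics = 2L,
                            harmonic_weights = c(1, 0.7)) {
  fs <- cfg$sample_rate
  stopifnot(duration_s > 0, f_start > f_end, f_end > 0, harmonics >= 1)
  if (harmonics * f_start >= fs / 2)
    stopf("highest harmonic (%g Hz) violates Nyquist (%g Hz)",
          harmonics * f_start, fs / 2)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  # hyperbolic sweep: 1/f linear in time
  finst <- 1 / (1 / f_start + (1 / f_end - 1 / f_start) * t / duration_s)
  phase <- 2 * pi * cumsum(finst) / fs
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))  # Hann taper
  call <- numeric(n)
  for (h in seq_len(harmonics)) {
    amp <- if (h <= length(harmonic_weights)) harmonic_weights[h] else
      harmonic_weights[length(harmonic_weights)]
    call <- call + amp * sin(h * phase)
  }
  call <- call * w
  structure(call, sample_rate = fs, instantaneous_frequency = finst)
}
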