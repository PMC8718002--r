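#' Cut the flower echo out of an impulse response
#'
#' Finds the strongest sample after a guard interval (which skips direct
#' crosstalk at the start of the IR) and returns a rectangular window of
#' `window_len` samples starting `pre_peak` samples before the peak. Errors
#' with "no echo found" if the peak does not exceed `noise_mult` times a
#' robust (MAD-based) estimate of the noise level in the search region.
#'
#' @param ir impulse response (numeric).
#' @param window_len window length in samples (default 1024).
#' @param sample_rate sampling rate in Hz.
#' @param guard_s guard interval in seconds skipped before the peak search.
#' @param pre_peak samples retained before the detected peak.
#' @param noise_mult detection threshold as a multiple of the noise SD.
#' @return numeric vector of length `window_len` with attributes `start`
#'   (1-based index into `ir`) and `peak` (index of the detected peak).
#' @export
extract_echo <- function(ir, window_len = 1024L, sample_rate = 5e5,
                         guard_s = 8e-4, pre_peak = 128L, noise_mult = 5) {
  n <- length(ir)
  if (n < window_len) stopf("IR shorter than the echo window")
  guard <- min(round(guard_s * sample_rate), n - window_len)
  search <- abs(ir[(guard + 1):n])
  # noise level from a 1-in-7 decimated sample of the search region (cheap,
  # robust to the sparse echo peaks)
  noise_sd <- mad(search[seq(1, length(search), by = 7)], center = 0)
  peak_rel <- which.max(search)
  if (noise_sd > 0 && search[peak_rel] < noise_mult * noise_sd)
    stopf("no echo found: peak %.3g below %g x noise SD %.3g",
          search[peak_rel], noise_mult, noise_sd)
  peak <- guard + peak_rel
  start <- max(1L, peak - as.integer(pre_peak))
  start <- min(start, n - window_len + 1L)
  structure(ir[start:(start + window_len - 1L)], start = start, peak = peak)
}

#' One-sided power spectrum of an echo segment
#'
#' Magnitude-squared FFT of the rectangular-windowed segment on the one-sided
#' frequency grid 0..Nyquist (spacing `fs / N`), scaled so that the total
#' spectral power equals the total sample energy (Parseval).
#'
#' @param segment numeric vector (typically the 1024-sample echo window).
#' @param sample_rate sampling rate in Hz.
#' @return object of class `power_spectrum`: list with `frequency` (Hz) and
#'   `power`.
#' @export
power_spectrum <- function(segment, sample_rate = 5e5) {
  n <- length(segment)
  X <- fft(segment)
  half <- seq_len(n %/% 2 + 1)
  pw <- Mod(X[half])^2 / n
  # double interior bins so one-sided power sums to the sample energy
  interior <- setdiff(half, c(1L, if (n %% 2 == 0) n %/% 2 + 1L))
  pw[interior] <- 2 * pw[interior]
  structure(list(frequency = (half - 1) * sample_rate / n, power = pw),
            class = "power_spectrum")
}

#' Calibrate a flower spectrum against the reference plate
#'
#' Spectral target strength as the dB difference between the flower echo
#' power spectrum and the reference-plate power spectrum measured through the
#' identical chain. Any common transmit/receive coloration cancels in the
#' difference. Frequencies outside the analysis band are flagged unreliable.
#'
#' @param flower_spectrum,plate_spectrum [power_spectrum()] objects on the
#'   same frequency grid.
#' @param band analysis band in Hz (default 40-160 kHz).
#' @param angle,plane optional metadata carried through.
#' @return object of class `ts_spectrum`: list with `frequency`, `ts_db`,
#'   `reliable` (logical), `angle`, `plane`.
#' @export
calibrate_ts <- function(flower_spectrum, plate_spectrum,
                         band = c(40e3, 160e3), angle = NA, plane = NA) {
  f <- flower_spectrum$frequency
  if (length(f) != length(plate_spectrum$frequency) ||
      max(abs(f - plate_spectrum$frequency)) > 1e-6)
    stopf("flower and plate spectra are on different frequency grids")
  inband <- f >= band[1] & f <= band[2]
  if (any(plate_spectrum$power[inband] == 0))
    stopf("plate spectrum has zero power inside the analysis band")
  ts <- power_to_db(flower_spectrum$power) -
    power_to_db(plate_spectrum$power)
  structure(list(frequency = f, ts_db = ts, reliable = inband,
                 angle = angle, plane = plane),
            class = "ts_spectrum")
}

#' Standard frequency bands for target-strength analysis
#'
#' The broad 40-160 kHz band (the typical bandwidth of a glossophagine
#' echolocation call) and four narrow bands with centre frequencies 45, 68,
#' 102 and 153 kHz and boundaries +/-20 percent around the centre.
#'
#' @return data frame with columns `name`, `f_low`, `f_high` (Hz).
#' @export
ts_bands <- function() {
  centers <- c(45e3, 68e3, 102e3, 153e3)
  data.frame(name = c("broad", "f45", "f68", "f102", "f153"),
             f_low = c(40e3, centers * 0.8),
             f_high = c(160e3, centers * 1.2),
             stringsAsFactors = FALSE)
}

#' Band-averaged target strength
#'
#' Converts the TS spectrum to linear power, averages the bins whose centre
#' frequency lies in the closed interval `[f_low, f_high]`, and converts back
#' to dB ("delog" averaging).
#'
#' @param ts a [calibrate_ts()] object.
#' @param band one row of [ts_bands()] or a list with `f_low`, `f_high`.
#' @return scalar dB.
#' @export
band_ts <- function(ts, band) {
  sel <- ts$frequency >= band$f_low & ts$frequency <= band$f_high
  if (!any(sel)) stopf("band [%g, %g] Hz contains no frequency bins",
                       band$f_low, band$f_high)
  delog_mean(ts$ts_db[sel])
}

#' Per-flower overall target strength
#'
#' Combines per-angle band TS values into one flower-level value: linear
#' (delog) mean over the angles of each plane, then the linear mean of the
#' plane values, reported in dB. Flowers scanned in a single plane use that
#' plane alone.
#'
#' @param azimuth numeric vector of per-angle band TS (dB) for the azimuth
#'   plane, or `NULL`.
#' @param elevation same for the elevation plane, or `NULL`.
#' @return scalar dB.
#' @export
overall_ts <- function(azimuth = NULL, elevation = NULL) {
  planes <- Filter(Negate(is.null), list(azimuth, elevation))
  if (length(planes) == 0) stopf("at least one plane is required")
  delog_mean(vapply(planes, delog_mean, numeric(1)))
}

# Vectorised per-scan processing: window every angle's echo (same peak
# search and windowing rule as extract_echo, batched over angles), batch the
# FFTs with mvfft, calibrate against the plate, and return the linear-power
# matrix (n_angles x n_bins) plus the frequency grid.
.scan_power_matrix <- function(scan, plate_ir, window_len = 1024L,
                               guard_s = 8e-4, pre_peak = 128L,
                               noise_mult = 5) {
  irs <- scan$irs
  na <- nrow(irs); n <- ncol(irs)
  if (n < window_len) stopf("IRs shorter than the echo window")
  guard <- min(round(guard_s * scan$sample_rate), n - window_len)
  A <- abs(irs[, (guard + 1):n, drop = FALSE])
  peak_rel <- max.col(A, ties.method = "first")
  peak_val <- A[cbind(seq_len(na), peak_rel)]
  sub <- A[, seq(1, ncol(A), by = 7), drop = FALSE]  # decimated, see docs
  noise_sd <- apply(sub, 1, mad, center = 0)
  low <- noise_sd > 0 & peak_val < noise_mult * noise_sd
  if (any(low))
    stopf("no echo found at %d of %d angles (peak below %g x noise SD)",
          sum(low), na, noise_mult)
  peak <- guard + peak_rel
  start <- pmin(pmax(peak - as.integer(pre_peak), 1L), n - window_len + 1L)
  if (all(start == start[1])) {                 # common case: aligned echoes
    segs <- t(irs[, start[1]:(start[1] + window_len - 1L), drop = FALSE])
  } else {
    lin <- outer(0:(window_len - 1L), start - 1L, `+`) * na +
      matrix(seq_len(na), window_len, na, byrow = TRUE)
    segs <- matrix(irs[lin], window_len, na)    # window_len x n_angles
  }
  plate <- as.numeric(extract_echo(plate_ir, window_len = window_len,
                                   sample_rate = scan$sample_rate,
                                   guard_s = guard_s, pre_peak = pre_peak,
                                   noise_mult = noise_mult))
  half <- seq_len(window_len %/% 2 + 1)
  Pw <- Mod(mvfft(segs)[half, , drop = FALSE])^2
  pl <- Mod(fft(plate)[half])^2
  if (any(pl[.band_bins(scan$sample_rate, window_len)] == 0))
    stopf("plate spectrum has zero power inside the analysis band")
  list(power_ratio = t(Pw / pl),                # n_angles x n_bins, linear
       frequency = (half - 1) * scan$sample_rate / window_len)
}

.band_bins <- function(sample_rate, n, band = c(40e3, 160e3)) {
  f <- (seq_len(n %/% 2 + 1) - 1) * sample_rate / n
  which(f >= band[1] & f <= band[2])
}

#' Directional spectrum of a scan
#'
#' The angle x frequency matrix of calibrated target strength for one scan
#' plane: each row is the TS spectrum at one angle of sound incidence (0
#' degrees = flower opening). Two-path interference makes the notch
#' frequencies shift with angle, the "spotted" pattern characteristic of
#' bell-shaped flowers.
#'
#' @param scan an `ir_scan` (see [simulate_scan()] or [read_scan()]).
#' @param plate_ir reference-plate impulse response processed identically.
#' @param window_len echo window length in samples.
#' @param ... further arguments to [extract_echo()].
#' @return matrix (n_angles x n_bins) of TS in dB with attributes `angles`
#'   and `frequency`.
#' @export
directional_spectrum <- function(scan, plate_ir, window_len = 1024L, ...) {
  pm <- .scan_power_matrix(scan, plate_ir, window_len = window_len, ...)
  out <- power_to_db(pm$power_ratio)
  attr(out, "angles") <- scan$angles
  attr(out, "frequency") <- pm$frequency
  out
}

#' Per-angle band target strength of a scan
#'
#' @inheritParams directional_spectrum
#' @param bands band table as from [ts_bands()].
#' @return matrix (n_angles x n_bands) of TS in dB, columns named by band.
#' @export
scan_band_ts <- function(scan, plate_ir, bands = ts_bands(),
                         window_len = 1024L, ...) {
  pm <- .scan_power_matrix(scan, plate_ir, window_len = window_len, ...)
  out <- sapply(seq_len(nrow(bands)), function(b) {
    sel <- pm$frequency >= bands$f_low[b] & pm$frequency <= bands$f_high[b]
    if (!any(sel)) stopf("band %s contains no frequency bins",
                         bands$name[b])
    power_to_db(rowMeans(pm$power_ratio[, sel, drop = FALSE]))
  })
  colnames(out) <- bands$name
  out
}

#' Simulate and process a flower set to a band-TS table
#'
#' The full measurement pipeline on synthetic flowers: draws each flower's
#' true broadband TS from the ground-truth model (including the Gaussian
#' flower-level residual), simulates both scan planes, windows and calibrates
#' every echo against the reference plate, and delog-averages per band over
#' angles and planes. This is the per-flower table the statistical analysis
#' consumes.
#'
#' @param flowers flower table from [sample_flowers()].
#' @param truth an [acoustic_truth()].
#' @param cfg a [sim_config()].
#' @param bands band table as from [ts_bands()].
#' @param seed integer seed for the flower-level TS residuals (defaults to
#'   `cfg$seed`).
#' @return data frame: `flower_id`, `species`, `code`, `family`, `syndrome`,
#'   `surface_area`, and one `ts_<band>` column per band (dB).
#' @export
flower_ts_table <- function(flowers, truth = acoustic_truth(),
                            cfg = sim_config(), bands = ts_bands(),
                            seed = cfg$seed) {
  plate <- plate_impulse_response(cfg)
  eps <- with_seed(seed, rnorm(nrow(flowers), sd = truth$noise_sd_db))
  ts_true <- expected_ts(flowers, truth) + eps
  vals <- t(vapply(seq_len(nrow(flowers)), function(i) {
    fl <- flowers[i, ]
    per_plane <- sapply(c("azimuth", "elevation"), function(pl) {
      scan <- simulate_scan(fl, plane = pl, truth = truth, cfg = cfg,
                            ts_db = ts_true[i])
      bt <- scan_band_ts(scan, plate, bands = bands)
      apply(bt, 2, delog_mean)
    })
    apply(per_plane, 1, delog_mean)
  }, numeric(nrow(bands))))
  colnames(vals) <- paste0("ts_", bands$name)
  cbind(flowers[, c("flower_id", "species", "code", "family", "syndrome",
                    "surface_area")],
        as.data.frame(vals))
}
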