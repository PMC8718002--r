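#' High-pass filter an echolocation call
#'
#' Zero-phase 4th-order Butterworth high-pass (applied forward and backward
#' with `signal::filtfilt`), used to remove low-frequency leakage from the
#' call before echo synthesis.
#'
#' @param call numeric waveform.
#' @param sample_rate sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz (default 5 kHz).
#' @return filtered waveform.
#' @export
highpass_call <- function(call, sample_rate = 5e5, cutoff = 5e3) {
  bf <- signal::butter(4, cutoff / (sample_rate / 2), type = "high")
  signal::filtfilt(bf, as.numeric(call))
}

#' Synthesize a flower echo from an impulse response
#'
#' Linear convolution of the (high-pass filtered) echolocation call with a
#' flower impulse response, trimmed or zero-padded to a fixed length so every
#' echo in a dataset has the same shape. Trimming starts at the first sample
#' of the convolution whose prefix energy is non-negligible, so the echo
#' onset is retained regardless of the IR's leading delay.
#'
#' @param ir impulse response (non-empty numeric).
#' @param call call waveform (already high-pass filtered; see
#'   [highpass_call()]).
#' @param length_out fixed output length in samples.
#' @return numeric echo of length `length_out`.
#' @export
make_echo <- function(ir, call, length_out = 2048L) {
  if (length(ir) == 0 || all(ir == 0)) stopf("empty impulse response")
  full <- .fft_convolve(c(as.numeric(ir), numeric(length(call))), call)
  mag <- abs(full)
  onset <- which(mag > 1e-9 * max(mag))[1]
  seg <- full[onset:length(full)]
  if (length(seg) >= length_out) seg[seq_len(length_out)]
  else c(seg, numeric(length_out - length(seg)))
}

#' Echo spectrogram
#'
#' Magnitude spectrogram with a 256-sample Hann window and a hop of 26
#' samples (90 percent overlap, rounded), converted to dB relative to the
#' spectrogram maximum with a -80 dB floor and min-max normalised to [0, 1].
#' This is the fixed-shape input representation of the CNN classifier.
#'
#' @param echo numeric waveform (length >= `window`).
#' @param window Hann window length in samples.
#' @param hop hop size in samples.
#' @param floor_db dynamic-range floor in dB (negative).
#' @return matrix (n_freq_bins x n_frames) in [0, 1]; silent input yields an
#'   all-zero (all-floor) spectrogram.
#' @export
echo_spectrogram <- function(echo, window = 256L, hop = 26L,
                             floor_db = -80) {
  n <- length(echo)
  if (n < window) stopf("echo shorter than the analysis window")
  n_frames <- (n - window) %/% hop + 1L
  idx <- outer(seq_len(window), (seq_len(n_frames) - 1L) * hop, `+`)
  frames <- matrix(echo[idx], nrow = window)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(window) - 1) / (window - 1))
  mag <- Mod(mvfft(frames * hann)[seq_len(window %/% 2 + 1L), ,
                                  drop = FALSE])
  peak <- max(mag)
  if (peak == 0) return(matrix(0, nrow = window %/% 2 + 1L,
                               ncol = n_frames))
  db <- 20 * log10(pmax(mag / peak, 10^(floor_db / 20)))
  (db - min(db)) / max(max(db) - min(db), .Machine$double.eps)
}
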