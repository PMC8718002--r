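#' Recover an impulse response from an MLS recording
#'
#' Slices the recording into whole MLS periods, discards the first period as
#' the transient, averages the next `n_average` periods, and circularly
#' cross-correlates the average with the MLS via FFT, normalising by the
#' sequence length. Because the circular autocorrelation of an MLS is `L` at
#' lag zero and `-1` elsewhere, the result is the periodised impulse response
#' (up to a small `O(1/L)` DC bias). Averaging `m` periods reduces the
#' residual noise power by `10 log10(m)` dB.
#'
#' @param recording numeric vector (at least `n_average + 1` whole periods).
#' @param mls the [generate_mls()] object used for playback.
#' @param n_average number of periods to average (default 50).
#' @return numeric impulse response of one period length.
#' @export
deconvolve <- function(recording, mls, n_average = 50L) {
  L <- length(mls$values)
  n_whole <- floor(length(recording) / L)
  if (n_whole < n_average + 1)
    stopf("recording holds %d whole periods; need %d (+1 transient)",
          n_whole, n_average)
  periods <- matrix(recording[seq_len((n_average + 1) * L)], nrow = L)
  avg <- rowMeans(periods[, -1, drop = FALSE])  # drop transient period
  S <- fft(mls$values)
  Y <- fft(avg)
  Re(fft(Y * Conj(S), inverse = TRUE)) / L / L
}
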