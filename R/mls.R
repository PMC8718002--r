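# Primitive feedback-polynomial tap positions (1-based) giving a maximal
# length sequence for each register order. One fixed polynomial per order.
.mls_taps <- list(
  `2` = c(2L, 1L),  `3` = c(3L, 2L),  `4` = c(4L, 3L),  `5` = c(5L, 3L),
  `6` = c(6L, 5L),  `7` = c(7L, 6L),  `8` = c(8L, 6L, 5L, 4L),
  `9` = c(9L, 5L),  `10` = c(10L, 7L), `11` = c(11L, 9L),
  `12` = c(12L, 6L, 4L, 1L), `13` = c(13L, 4L, 3L, 1L),
  `14` = c(14L, 5L, 3L, 1L), `15` = c(15L, 14L),
  `16` = c(16L, 15L, 13L, 4L), `17` = c(17L, 14L), `18` = c(18L, 11L),
  `19` = c(19L, 6L, 2L, 1L), `20` = c(20L, 17L), `21` = c(21L, 19L),
  `22` = c(22L, 21L), `23` = c(23L, 18L), `24` = c(24L, 23L, 22L, 17L))

#' Generate a maximum length sequence (MLS)
#'
#' Produces the +/-1 output of a maximal linear-feedback shift register of the
#' given order, length `2^order - 1`. An MLS is a periodic pseudorandom binary
#' sequence whose circular autocorrelation is `L` at lag zero and `-1` at
#' every other lag, which makes it an ideal excitation for impulse-response
#' measurement by cross-correlation. The default order 14 gives the 16383
#' sample sequence that lasts about 33 ms at 500 kHz.
#'
#' @param order shift-register order, 2..24. One fixed primitive feedback
#'   polynomial is used per order.
#' @param sample_rate playback sampling rate in Hz (metadata).
#' @return An object of class `mls` with elements `values` (+/-1 vector),
#'   `order` and `sample_rate`.
#' @examples
#' m <- generate_mls(3)
#' length(m$values)  # 7
#' @export
generate_mls <- function(order = 14L, sample_rate = 5e5) {
  order <- as.integer(order)
  key <- as.character(order)
  if (is.na(order) || !key %in% names(.mls_taps))
    stopf("unsupported MLS order %s (supported: 2..24)", order)
  values <- .lfsr_sequence(order, .mls_taps[[key]])
  structure(list(values = values, order = order, sample_rate = sample_rate),
            class = "mls")
}

#' @export
print.mls <- function(x, ...) {
  cat(sprintf("MLS of order %d: %d samples (%.3f ms at %g Hz)\n",
              x$order, length(x$values),
              1000 * length(x$values) / x$sample_rate, x$sample_rate))
  invisible(x)
}

#' Circular autocorrelation
#'
#' FFT-based circular autocorrelation, used to verify the MLS identity
#' (`L` at lag zero, `-1` elsewhere).
#'
#' @param x numeric vector.
#' @return numeric vector of the same length (lags 0..L-1).
#' @export
circular_autocorrelation <- function(x) {
  X <- fft(x)
  Re(fft(X * Conj(X), inverse = TRUE)) / length(x)
}

#' Period accounting for an MLS recording
#'
#' How many whole MLS periods a recording of the given duration holds, and how
#' many are usable for averaging once the first period is discarded as the
#' transient (the convention used by [deconvolve()]). A 2 s recording of an
#' order-14 MLS at 500 kHz holds 61 whole periods, 60 usable.
#'
#' @param duration_s recording duration in seconds.
#' @param order MLS order.
#' @param sample_rate sampling rate in Hz.
#' @return list with `whole`, `usable` and `period_samples`.
#' @export
mls_period_count <- function(duration_s = 2, order = 14L, sample_rate = 5e5) {
  period <- 2^as.integer(order) - 1
  whole <- floor(duration_s * sample_rate / period)
  list(whole = whole, usable = max(whole - 1, 0), period_samples = period)
}
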