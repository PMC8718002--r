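#' Minimal WAV input / output
#'
#' Reads and writes RIFF/WAVE files in 16-bit PCM or 32-bit IEEE float,
#' mono, which covers ultrasound recordings exchanged with acquisition
#' software. `read_wav()` refuses to resample: the caller sees the file's
#' own sample rate and must handle mismatches explicitly.
#'
#' @param path file path.
#' @return `read_wav()`: list with `samples` (numeric in [-1, 1] for PCM) and
#'   `sample_rate`. `write_wav()`: the path, invisibly.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stopf("%s is not a RIFF file", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stopf("%s is not a WAVE file", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        sample_rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (id == "data") {
      data <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stopf("malformed WAV file %s", path)
  if (fmt$channels != 1) stopf("only mono WAV supported")
  samples <- if (fmt$audio_format == 3 && fmt$bits == 32) {
    readBin(data, "numeric", length(data) / 4, size = 4, endian = "little")
  } else if (fmt$audio_format == 1 && fmt$bits == 16) {
    readBin(data, "integer", length(data) / 2, size = 2, signed = TRUE,
            endian = "little") / 32768
  } else stopf("unsupported WAV format (format %d, %d bit)",
               fmt$audio_format, fmt$bits)
  list(samples = samples, sample_rate = fmt$sample_rate)
}

#' @rdname read_wav
#' @param samples numeric vector.
#' @param sample_rate sampling rate in Hz.
#' @param bits 32 (IEEE float, default) or 16 (PCM).
#' @export
write_wav <- function(samples, path, sample_rate = 5e5, bits = 32) {
  stopifnot(bits %in% c(16, 32))
  bytes <- bits / 8
  data_size <- length(samples) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(if (bits == 32) 3 else 1), con, size = 2,
           endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes), con, size = 4,
           endian = "little")
  writeBin(as.integer(bytes), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 32) {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(pmax(pmin(round(samples * 32767), 32767), -32768)),
             con, size = 2, endian = "little")
  }
  invisible(path)
}
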