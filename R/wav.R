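#' Write a mono waveform to a RIFF/PCM WAV file
#'
#' Samples are clipped to \[-1, 1\] and quantized to signed integer PCM at the
#' requested bit depth (16 by default, matching clinical voice-recording
#' practice). The in-memory pipeline stays in floating point; quantization
#' happens only here.
#'
#' @param samples numeric vector of amplitudes in \[-1, 1\]
#' @param fs sampling rate in Hz
#' @param path output file path
#' @param bit_depth bits per sample (16 supported)
#' @return `path`, invisibly
#' @export
write_wav <- function(samples, fs, path, bit_depth = 16L) {
  if (bit_depth != 16L) stopf("only 16-bit PCM output is supported")
  x <- pmin(1, pmax(-1, as.numeric(samples)))
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs) * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit RIFF/PCM WAV file
#'
#' @param path file path
#' @return list with `samples` (numeric in \[-1, 1\]) and `fs`
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stopf("not a RIFF file: %s", path)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stopf("not a WAVE file: %s", path)
  fs <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      channels <- fmt[2]
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) readBin(con, raw(), n = sz - 16)
    } else if (identical(id, "data")) {
      samples <- readBin(con, integer(), n = sz %/% 2, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      readBin(con, raw(), n = sz)
    }
  }
  if (is.null(samples)) stopf("no data chunk found in %s", path)
  if (!identical(channels, 1L)) stopf("only mono WAV files are supported")
  if (!identical(bits, 16L)) stopf("only 16-bit PCM is supported")
  list(samples = samples / 32767, fs = fs)
}
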