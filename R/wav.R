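#' Write a mono waveform as 16-bit PCM WAV
#'
#' Minimal RIFF/WAVE writer (16-bit PCM, single channel). The waveform is
#' scaled by `scale` and clipped to [-1, 1] before quantization.
#'
#' @param x numeric waveform in [-1, 1] (values outside are clipped).
#' @param path output file path.
#' @param fs sample rate in Hz.
#' @param scale linear gain applied before quantization.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, fs = 44100, scale = 1) {
  x <- pmin(1, pmax(-1, x * scale))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Counterpart of [write_wav()]; supports the canonical 16-bit PCM mono
#' layout only.
#'
#' @param path input file path.
#' @return list with `x` (waveform in [-1, 1]) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only mono PCM supported")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      bits <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (bits[2] != 16L) stop("only 16-bit PCM supported")
      seek(con, size - 16, origin = "current")
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", size %/% 2L, size = 2, endian = "little")
      return(list(x = pcm / 32767, fs = fs))
    } else {
      seek(con, size, origin = "current")
    }
  }
}
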