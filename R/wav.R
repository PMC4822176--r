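# Minimal 16-bit PCM mono WAV read/write (RIFF).  Only the subset of the
# format the package produces and consumes is supported.

#' Write a waveform as a 16-bit PCM mono WAV file
#'
#' @param wave numeric samples in `[-1, 1]`, or a `voice_wave` from
#'   [generate_voice_wav()] (in which case `sample_rate` is taken from it).
#' @param path output file path.
#' @param sample_rate samples per second.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, sample_rate = 8000L) {
  if (inherits(wave, "voice_wave")) {
    sample_rate <- wave$sample_rate
    wave <- wave$wave
  }
  stopifnot(is.numeric(wave), length(wave) >= 1L)
  pcm <- as.integer(round(pmin(pmax(wave, -1), 1) * 32767))
  data_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(c(1L, 1L), con, size = 2, endian = "little")    # PCM, mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")   # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path WAV file path.
#' @return list with `wave` (numeric in `[-1, 1]`) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop_bad_arg("not a RIFF file: ", path)
  readBin(con, integer(), 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop_bad_arg("not a WAVE file: ", path)
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L)
      stop_bad_arg("no data chunk found in ", path)
    size <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), 2, size = 2, endian = "little")
      if (fmt[1L] != 1L || fmt[2L] != 1L)
        stop_bad_arg("only PCM mono WAV is supported")
      sample_rate <- readBin(con, integer(), 1, size = 4, endian = "little")
      readBin(con, integer(), 1, size = 4, endian = "little")
      bits <- readBin(con, integer(), 2, size = 2, endian = "little")[2L]
      if (bits != 16L) stop_bad_arg("only 16-bit WAV is supported")
      if (size > 16L) readBin(con, raw(), size - 16L)
    } else if (id == "data") {
      pcm <- readBin(con, integer(), size %/% 2L, size = 2, endian = "little")
      if (is.null(sample_rate)) stop_bad_arg("data chunk before fmt chunk")
      return(list(wave = pcm / 32767, sample_rate = sample_rate))
    } else {
      readBin(con, raw(), size)
    }
  }
}
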