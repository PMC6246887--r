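# Minimal 16-bit PCM RIFF/WAVE I/O. Mono, little-endian; enough to round-trip
# the synthetic audio fixtures.

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples numeric vector in [-1, 1] (clipped otherwise).
#' @param path output path.
#' @param rate sample rate in Hz.
#' @export
write_wav <- function(samples, path, rate = 8000) {
  s <- as.integer(round(pmin(pmax(samples, -1), 1) * 32767))
  n <- length(s)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")   # fmt chunk size
  writeBin(as.integer(1), con, size = 2, endian = "little")    # PCM
  writeBin(as.integer(1), con, size = 2, endian = "little")    # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2), con, size = 4, endian = "little") # byte rate
  writeBin(as.integer(2), con, size = 2, endian = "little")    # block align
  writeBin(as.integer(16), con, size = 2, endian = "little")   # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(s, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path input path.
#' @return list with `samples` (numeric in [-1, 1]) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV is supported")
      channels <- fmt[2]
      rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit WAV is supported")
      extra <- size - 16L
      if (extra > 0) invisible(readBin(con, raw(), n = extra))
    } else if (id == "data") {
      samples <- readBin(con, integer(), n = size %/% 2L, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
  if (is.null(samples)) stop("no data chunk found")
  if (!is.null(channels) && channels != 1L) stop("only mono WAV is supported")
  list(samples = samples / 32767, rate = rate)
}
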