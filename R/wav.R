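#' Write audio to a 16-bit PCM WAV file
#'
#' Writes mono, 16-bit, little-endian PCM in the canonical 44-byte RIFF
#' layout at the signal's sample rate.  The audio must already be
#' normalized (max |sample| <= 1, see \code{\link{normalizeQuantize}});
#' samples are scaled by 32767 and rounded, so reading the file back
#' reproduces them within one quantization step (1/32768).
#'
#' @param audio a normalized, non-empty \linkS4class{AudioSignal}
#' @param path output file path
#' @return \code{path}, invisibly
#' @seealso \code{\link{readWav}}
#' @export
writeWav <- function(audio, path) {
  stopifnot(is(audio, "AudioSignal"))
  n <- length(audio@samples)
  if (n == 0L) stop("cannot write empty audio")
  if (audio@sampleRate < 1L) stop("sample rate must be >= 1")
  if (max(abs(audio@samples)) > 1 + 1e-12)
    stop("audio must be normalized to |sample| <= 1 before writing")
  pcm <- as.integer(pmin(32767, pmax(-32768, round(audio@samples * 32767))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")        # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")         # PCM
  writeBin(1L, con, size = 2, endian = "little")         # mono
  writeBin(audio@sampleRate, con, size = 4, endian = "little")
  writeBin(2L * audio@sampleRate, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")         # block align
  writeBin(16L, con, size = 2, endian = "little")        # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' Parses RIFF/WAVE chunks, requiring mono 16-bit PCM as written by
#' \code{\link{writeWav}}.  Samples are returned on the [-1, 1] scale
#' (divided by 32767).
#'
#' @param path WAV file path
#' @return an \linkS4class{AudioSignal}
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", size = 4, endian = "little")   # overall size
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  sampleRate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L)
      stop("no data chunk found in ", path)
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV is supported")
      if (fmt[2] != 1L) stop("only mono WAV is supported")
      sampleRate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")  # byte rate
      ba <- readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit WAV is supported")
      if (size > 16L) readBin(con, "raw", n = size - 16L)
    } else if (id == "data") {
      if (is.null(sampleRate)) stop("data chunk before fmt chunk in ", path)
      pcm <- readBin(con, "integer", n = size / 2, size = 2,
                     endian = "little")
      return(audioSignal(pcm / 32767, sampleRate))
    } else {
      readBin(con, "raw", n = size + size %% 2)
    }
  }
}
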