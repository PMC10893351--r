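#' Naive real-part audification (demonstrates aliasing)
#'
#' Takes only the real channel of the quadrature FID as audio samples, at a
#' sample rate equal to the spectral width.  Because a real signal cannot
#' distinguish positive from negative frequencies, every display frequency
#' above the Nyquist frequency SW/2 folds back and is heard at
#' \code{aliasFrequency(f, SW)}.  This path exists to demonstrate the
#' artefact the ZPFD path removes.
#'
#' @param fid an \linkS4class{FID}
#' @return an \linkS4class{AudioSignal} at rate round(SW)
#' @seealso \code{\link{zpfdAudify}} for the alias-free path
#' @export
realAudify <- function(fid) {
  stopifnot(is(fid, "FID"))
  audioSignal(Re(fid@samples), round(fid@params@sw))
}

#' Alias-free audification by zero padding in the frequency domain (ZPFD)
#'
#' The anti-aliasing procedure at the heart of the package.  Given the
#' N-point display-axis spectrum: (1) build a 2N-point frequency vector
#' whose positive-frequency half (display frequencies [0, SW) at resolution
#' SW/N) holds the spectrum values and whose other N bins are zero;
#' (2) inverse-DFT it to a 2N-point augmented FID; (3) play the real part
#' at twice the original spectral width.  Doubling both the point count and
#' the rate preserves the acquisition-time duration, and with all content
#' confined to [0, SW) — below the new Nyquist frequency SW — the real part
#' alone carries every resonance at its true display frequency: no folding.
#'
#' The output is not normalized; pass it through
#' \code{\link{normalizeQuantize}} before \code{\link{writeWav}}.
#'
#' @param spectrum a \linkS4class{Spectrum} of N points
#' @return an \linkS4class{AudioSignal} of 2N samples at rate round(2 * SW)
#' @export
zpfdAudify <- function(spectrum) {
  stopifnot(is(spectrum, "Spectrum"))
  n <- length(spectrum@values)
  if (n == 0L) stop("cannot audify an empty spectrum")
  padded <- c(spectrum@values, complex(real = rep(0, n)))
  augmented <- stats::fft(padded, inverse = TRUE) / (2 * n)
  audioSignal(Re(augmented), round(2 * spectrum@params@sw))
}

#' Scale audio to a target peak amplitude
#'
#' Linearly scales the samples so the maximum absolute value equals
#' \code{headroom} (default 0.9, leaving margin below full scale before
#' 16-bit quantization).  All-zero input passes through unchanged.
#'
#' @param audio an \linkS4class{AudioSignal}
#' @param headroom target peak amplitude, in (0, 1]
#' @return the scaled \linkS4class{AudioSignal}
#' @export
normalizeQuantize <- function(audio, headroom = 0.9) {
  stopifnot(is(audio, "AudioSignal"))
  if (length(audio@samples) == 0L) stop("audio must be non-empty")
  if (length(headroom) != 1L || !is.finite(headroom) || headroom <= 0 ||
      headroom > 1)
    stop("headroom must be a single value in (0, 1]")
  peak <- max(abs(audio@samples))
  if (peak == 0) return(audio)
  audioSignal(audio@samples * (headroom / peak), audio@sampleRate)
}

#' Detect the frequency components of an audio signal
#'
#' The closed-loop analyzer used throughout the package's checks, playing
#' the role a spectrum-plot tool plays for a listener: it computes the DFT
#' magnitude of the (real) audio over [0, sampleRate/2], finds local maxima
#' above \code{threshold} times the global maximum, merges maxima that fall
#' within one frequency-resolution bin of each other (keeping the larger),
#' and returns them sorted by frequency.  No window function is applied:
#' the decaying signals this package produces are self-windowed.
#'
#' @param audio an \linkS4class{AudioSignal} (non-empty)
#' @param threshold fraction of the global maximum magnitude below which
#'   maxima are ignored, in (0, 1); default 0.05
#' @return a data.frame with columns \code{frequency} (Hz) and
#'   \code{magnitude} (relative to the global maximum); zero rows for
#'   silent audio
#' @examples
#' fx <- fourPeakFixture()
#' analyzeAudio(zpfdAudify(fourierTransform(fx$fid)))$frequency
#' @export
analyzeAudio <- function(audio, threshold = 0.05) {
  stopifnot(is(audio, "AudioSignal"))
  n <- length(audio@samples)
  if (n == 0L) stop("audio must be non-empty")
  if (length(threshold) != 1L || !is.finite(threshold) || threshold <= 0 ||
      threshold >= 1)
    stop("threshold must be a single value in (0, 1)")
  mag <- Mod(stats::fft(audio@samples))
  half <- seq_len(floor(n / 2) + 1L)          # [0, sampleRate/2]
  mag <- mag[half]
  freq <- (half - 1) * audio@sampleRate / n
  top <- max(mag)
  if (top == 0)
    return(data.frame(frequency = numeric(), magnitude = numeric()))
  m <- length(mag)
  left <- c(-Inf, mag[-m])
  right <- c(mag[-1], -Inf)
  idx <- which(mag > left & mag >= right & mag >= threshold * top)
  if (length(idx) == 0L)
    return(data.frame(frequency = numeric(), magnitude = numeric()))
  # merge maxima closer than one resolution bin, keeping the larger
  keep <- integer()
  cur <- idx[1]
  for (i in idx[-1]) {
    if (i - cur <= 1L) {
      if (mag[i] > mag[cur]) cur <- i
    } else {
      keep <- c(keep, cur)
      cur <- i
    }
  }
  keep <- c(keep, cur)
  data.frame(frequency = freq[keep], magnitude = mag[keep] / top)
}
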