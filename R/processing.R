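#' Exponential apodization (line broadening)
#'
#' Multiplies the FID by the exponential window exp(-pi * lb * t), the
#' standard "EM" weighting: every Lorentzian line in the resulting spectrum
#' is broadened by exactly \code{lb} Hz (Lorentzian widths add under this
#' convolution), trading resolution for signal-to-noise.  Audibly, the decay
#' speeds up and the noise tail is suppressed.
#'
#' @param fid an \linkS4class{FID}
#' @param lb line broadening in Hz (>= 0; 0 is the identity)
#' @return the apodized \linkS4class{FID}
#' @export
apodizeExponential <- function(fid, lb) {
  stopifnot(is(fid, "FID"))
  if (length(lb) != 1L || !is.finite(lb) || lb < 0)
    stop("lb must be a single finite value >= 0")
  if (lb == 0) return(fid)
  k <- seq_along(fid@samples) - 1
  newFid(fid@samples * exp(-pi * lb * k * fid@params@dwell), fid@params)
}

#' Zero-fill an FID
#'
#' Appends zeros so the length becomes \code{factor} times the original
#' number of points.  The dwell time (hence the spectral width) is
#' unchanged; the frequency grid after transformation is refined by the
#' same factor.  Powers of two keep the transform length a power of two.
#'
#' @param fid an \linkS4class{FID}
#' @param factor integer >= 1 (1 is the identity)
#' @return the zero-filled \linkS4class{FID} with updated point count
#' @export
zeroFill <- function(fid, factor) {
  stopifnot(is(fid, "FID"))
  if (length(factor) != 1L || !is.finite(factor) || factor < 1 ||
      factor != round(factor))
    stop("factor must be a single integer >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(fid)
  n <- length(fid@samples)
  p <- fid@params
  params <- acquisitionParams(sw = p@sw, nPoints = n * factor,
                              refOffset = p@refOffset,
                              spectrometerFreq = p@spectrometerFreq)
  newFid(c(fid@samples, complex(real = rep(0, n * (factor - 1L)))), params)
}

#' Fourier transform an FID to the display-axis spectrum
#'
#' Computes the complex DFT of the FID (forward transform unnormalized) and
#' expresses the result on the display axis: frequencies ascending over
#' [0, SW) in steps of SW/N, 0 Hz at the rightmost point of the plotted
#' spectrum.  The NMR plotting convention rotates the raw DFT output by N/2
#' bins to obtain the carrier-centered range -1/(2 dt) .. (N/2 - 1)/(N dt);
#' re-expressing that carrier-centered spectrum back on the [0, SW) display
#' axis undoes the rotation, so the stored vector is the DFT output in
#' natural bin order with bin m at display frequency m * SW / N.
#'
#' @param fid an \linkS4class{FID} (non-empty)
#' @return a \linkS4class{Spectrum}
#' @seealso \code{\link{inverseTransform}} for the exact inverse
#' @export
fourierTransform <- function(fid) {
  stopifnot(is(fid, "FID"))
  if (length(fid@samples) == 0L) stop("cannot transform an empty FID")
  newSpectrum(stats::fft(fid@samples), fid@params)
}

#' Inverse Fourier transform a spectrum back to an FID
#'
#' The exact inverse of \code{\link{fourierTransform}}: the inverse DFT
#' carries the 1/N normalization, so the round trip reproduces the FID to
#' floating-point accuracy.
#'
#' @param spectrum a \linkS4class{Spectrum} (non-empty)
#' @return an \linkS4class{FID}
#' @export
inverseTransform <- function(spectrum) {
  stopifnot(is(spectrum, "Spectrum"))
  n <- length(spectrum@values)
  if (n == 0L) stop("cannot transform an empty spectrum")
  newFid(stats::fft(spectrum@values, inverse = TRUE) / n, spectrum@params)
}

#' Reference-offset correction in the time domain
#'
#' Referencing against a standard (e.g. TMS) shifts every spectral
#' frequency by a constant, so the rightmost point of the spectrum is not
#' 0 Hz.  For the audio pitch to match the frequencies read off the
#' spectrum, the offset is removed in the time domain by multiplying the
#' FID by exp(-i 2 pi df t): every peak's display frequency moves by
#' -df (mod SW).
#'
#' @param fid an \linkS4class{FID}
#' @param deltaF frequency offset in Hz, |deltaF| < SW
#' @return the corrected \linkS4class{FID}
#' @export
offsetCorrect <- function(fid, deltaF) {
  stopifnot(is(fid, "FID"))
  if (length(deltaF) != 1L || !is.finite(deltaF))
    stop("deltaF must be a single finite value")
  if (deltaF == 0) return(fid)
  k <- seq_along(fid@samples) - 1
  newFid(fid@samples * exp(-1i * 2 * pi * deltaF * k * fid@params@dwell),
         fid@params)
}
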