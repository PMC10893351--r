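#' @import methods
NULL

#' Acquisition parameters of a quadrature-detected NMR experiment
#'
#' Holds the handful of numbers that govern every frequency/index mapping in
#' the package: the spectral width SW (Hz), the number of complex points N,
#' the dwell time (s), the reference offset (Hz) and, optionally, the
#' spectrometer observe frequency (MHz) for ppm conversion.  Under quadrature
#' sampling the dwell time is the reciprocal of the spectral width; the
#' validity method enforces this to 1e-6 relative.
#'
#' @slot sw spectral width in Hz (> 0)
#' @slot nPoints number of complex points (>= 2)
#' @slot dwell dwell time in seconds, 1/sw
#' @slot refOffset reference frequency offset in Hz (0 when the rightmost
#'   spectral point is 0 Hz)
#' @slot spectrometerFreq observe frequency in MHz, or NA when unknown
#' @export
setClass("AcquisitionParams",
  representation(
    sw = "numeric",
    nPoints = "integer",
    dwell = "numeric",
    refOffset = "numeric",
    spectrometerFreq = "numeric"
  ),
  prototype(
    sw = 1000, nPoints = 1024L, dwell = 1e-3, refOffset = 0,
    spectrometerFreq = NA_real_
  )
)

setValidity("AcquisitionParams", function(object) {
  msgs <- character()
  if (length(object@sw) != 1L || !is.finite(object@sw) || object@sw <= 0)
    msgs <- c(msgs, "sw must be a single finite value > 0")
  if (length(object@nPoints) != 1L || is.na(object@nPoints) ||
      object@nPoints < 2L)
    msgs <- c(msgs, "nPoints must be a single integer >= 2")
  if (length(object@dwell) != 1L || !is.finite(object@dwell) ||
      object@dwell <= 0)
    msgs <- c(msgs, "dwell must be a single finite value > 0")
  else if (length(object@sw) == 1L && is.finite(object@sw) && object@sw > 0 &&
           abs(object@dwell * object@sw - 1) > 1e-6)
    msgs <- c(msgs, "dwell must equal 1/sw (quadrature convention)")
  if (length(object@refOffset) != 1L || !is.finite(object@refOffset))
    msgs <- c(msgs, "refOffset must be a single finite value")
  if (length(object@spectrometerFreq) != 1L ||
      (!is.na(object@spectrometerFreq) &&
       (!is.finite(object@spectrometerFreq) || object@spectrometerFreq <= 0)))
    msgs <- c(msgs, "spectrometerFreq must be NA or a single value > 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct acquisition parameters
#'
#' @param sw spectral width in Hz
#' @param nPoints number of complex points
#' @param refOffset reference offset in Hz (default 0)
#' @param spectrometerFreq observe frequency in MHz (default NA)
#' @return an \linkS4class{AcquisitionParams} object with dwell = 1/sw
#' @examples
#' acquisitionParams(sw = 1000, nPoints = 4096)
#' @export
acquisitionParams <- function(sw, nPoints, refOffset = 0,
                              spectrometerFreq = NA_real_) {
  new("AcquisitionParams",
      sw = as.numeric(sw), nPoints = as.integer(nPoints),
      dwell = 1 / as.numeric(sw), refOffset = as.numeric(refOffset),
      spectrometerFreq = as.numeric(spectrometerFreq))
}

#' Free induction decay: a complex time-domain NMR signal
#'
#' The transient signal induced in the receiver coil after excitation,
#' acquired in quadrature as a sequence of complex points d_k, k = 0..N-1,
#' sampled every dwell seconds.
#'
#' @slot samples complex vector of length nPoints(params)
#' @slot params an \linkS4class{AcquisitionParams}
#' @export
setClass("FID",
  representation(samples = "complex", params = "AcquisitionParams"))

setValidity("FID", function(object) {
  msgs <- character()
  if (length(object@samples) != object@params@nPoints)
    msgs <- c(msgs, "length(samples) must equal params nPoints")
  if (anyNA(object@samples) || any(!is.finite(Re(object@samples))) ||
      any(!is.finite(Im(object@samples))))
    msgs <- c(msgs, "all FID samples must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct an FID
#' @param samples complex vector
#' @param params \linkS4class{AcquisitionParams} whose nPoints matches
#' @return an \linkS4class{FID}
#' @export
newFid <- function(samples, params) {
  new("FID", samples = as.complex(samples), params = params)
}

#' Frequency-domain NMR spectrum on the display axis
#'
#' Complex spectral values in ascending display-frequency order.  The display
#' axis puts 0 Hz at the rightmost (most shielded) point of the plotted
#' spectrum and increases leftward, covering [0, SW) in steps of SW/N when
#' the reference offset is zero.
#'
#' @slot values complex vector in ascending display-frequency order
#' @slot axis display frequencies in Hz, strictly increasing, step SW/N
#' @slot params the \linkS4class{AcquisitionParams} of the source FID
#' @export
setClass("Spectrum",
  representation(values = "complex", axis = "numeric",
                 params = "AcquisitionParams"))

setValidity("Spectrum", function(object) {
  msgs <- character()
  if (length(object@values) != length(object@axis))
    msgs <- c(msgs, "values and axis must have equal length")
  if (length(object@axis) >= 2L) {
    d <- diff(object@axis)
    step <- object@params@sw / length(object@axis)
    if (any(d <= 0) || any(abs(d - step) > 1e-9 * object@params@sw))
      msgs <- c(msgs, "axis must be strictly increasing with constant step SW/N")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Spectrum
#' @param values complex spectral values, ascending display frequency
#' @param params \linkS4class{AcquisitionParams}
#' @return a \linkS4class{Spectrum}; the axis is refOffset + (0:(N-1))*SW/N
#' @export
newSpectrum <- function(values, params) {
  n <- length(values)
  ax <- params@refOffset + (seq_len(n) - 1) * params@sw / n
  new("Spectrum", values = as.complex(values), axis = ax, params = params)
}

#' Real-valued audio samples with a sample rate
#'
#' Pre-quantization audio: real samples plus an integer sample rate in Hz.
#' Normalize with \code{\link{normalizeQuantize}} before writing to WAV.
#'
#' @slot samples numeric vector of finite values
#' @slot sampleRate integer sample rate in Hz (> 0)
#' @export
setClass("AudioSignal",
  representation(samples = "numeric", sampleRate = "integer"))

setValidity("AudioSignal", function(object) {
  msgs <- character()
  if (length(object@sampleRate) != 1L || is.na(object@sampleRate) ||
      object@sampleRate < 1L)
    msgs <- c(msgs, "sampleRate must be a single integer >= 1")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    msgs <- c(msgs, "all audio samples must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AudioSignal
#' @param samples numeric vector
#' @param sampleRate sample rate in Hz
#' @return an \linkS4class{AudioSignal}
#' @export
audioSignal <- function(samples, sampleRate) {
  new("AudioSignal", samples = as.numeric(samples),
      sampleRate = as.integer(round(sampleRate)))
}

## ---- accessors -----------------------------------------------------------

#' @describeIn acquisitionParams spectral width in Hz
#' @param object an object carrying acquisition parameters
#' @export
setGeneric("sweepWidth", function(object) standardGeneric("sweepWidth"))
#' @export
setMethod("sweepWidth", "AcquisitionParams", function(object) object@sw)
#' @export
setMethod("sweepWidth", "FID", function(object) object@params@sw)
#' @export
setMethod("sweepWidth", "Spectrum", function(object) object@params@sw)

#' Number of complex points
#' @param object an \code{AcquisitionParams}, \code{FID} or \code{Spectrum}
#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))
#' @export
setMethod("nPoints", "AcquisitionParams", function(object) object@nPoints)
#' @export
setMethod("nPoints", "FID", function(object) length(object@samples))
#' @export
setMethod("nPoints", "Spectrum", function(object) length(object@values))

#' Dwell time in seconds
#' @param object an object carrying acquisition parameters
#' @export
setGeneric("dwellTime", function(object) standardGeneric("dwellTime"))
#' @export
setMethod("dwellTime", "AcquisitionParams", function(object) object@dwell)
#' @export
setMethod("dwellTime", "FID", function(object) object@params@dwell)

#' Acquisition parameters of an object
#' @param object an \code{FID} or \code{Spectrum}
#' @export
setGeneric("acqParams", function(object) standardGeneric("acqParams"))
#' @export
setMethod("acqParams", "FID", function(object) object@params)
#' @export
setMethod("acqParams", "Spectrum", function(object) object@params)

#' Raw samples of a time-domain or audio object
#' @param object an \code{FID} (complex) or \code{AudioSignal} (numeric)
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @export
setMethod("samples", "FID", function(object) object@samples)
#' @export
setMethod("samples", "AudioSignal", function(object) object@samples)

#' Complex values of a spectrum
#' @param object a \code{Spectrum}
#' @export
setGeneric("specValues", function(object) standardGeneric("specValues"))
#' @export
setMethod("specValues", "Spectrum", function(object) object@values)

#' Display-frequency axis of a spectrum, in Hz
#' @param object a \code{Spectrum}
#' @export
setGeneric("displayAxis", function(object) standardGeneric("displayAxis"))
#' @export
setMethod("displayAxis", "Spectrum", function(object) object@axis)

#' Sample rate of an audio signal, in Hz
#' @param object an \code{AudioSignal}
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @export
setMethod("sampleRate", "AudioSignal",
          function(object) object@sampleRate)

#' Duration in seconds
#' @param object an \code{FID} (N * dwell) or \code{AudioSignal}
#'   (samples / rate)
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))
#' @export
setMethod("duration", "FID",
          function(object) length(object@samples) * object@params@dwell)
#' @export
setMethod("duration", "AudioSignal",
          function(object) length(object@samples) / object@sampleRate)

## ---- show ----------------------------------------------------------------

setMethod("show", "AcquisitionParams", function(object) {
  cat(sprintf("AcquisitionParams: SW = %g Hz, N = %d, dwell = %g s, offset = %g Hz",
              object@sw, object@nPoints, object@dwell, object@refOffset))
  if (!is.na(object@spectrometerFreq))
    cat(sprintf(", observe = %g MHz", object@spectrometerFreq))
  cat("\n")
})

setMethod("show", "FID", function(object) {
  cat(sprintf("FID: %d complex points, %g s acquisition (SW = %g Hz)\n",
              length(object@samples), duration(object), object@params@sw))
})

setMethod("show", "Spectrum", function(object) {
  n <- length(object@values)
  cat(sprintf("Spectrum: %d points, display axis [%g, %g] Hz (step %g Hz)\n",
              n, object@axis[1], object@axis[n], object@params@sw / n))
})

setMethod("show", "AudioSignal", function(object) {
  cat(sprintf("AudioSignal: %d samples at %d Hz (%.3f s), peak |s| = %.4g\n",
              length(object@samples), object@sampleRate, duration(object),
              if (length(object@samples)) max(abs(object@samples)) else 0))
})
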