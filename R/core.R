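#' Fold a display frequency across the Nyquist frequency
#'
#' When only the real channel of a quadrature FID is played back, any
#' component above the Nyquist frequency (half the spectral width) is
#' reflected back into the lower half of the band: a resonance at display
#' frequency f > SW/2 is heard at SW - f.  This closed form predicts where
#' a resonance lands in real-part-only audio.
#'
#' @param f display frequency in Hz, in [0, sw)
#' @param sw spectral width in Hz (> 0)
#' @return the apparent frequency, in [0, sw/2]
#' @examples
#' aliasFrequency(750, 1000)  # 250
#' aliasFrequency(300, 1000)  # 300 (below Nyquist: unchanged)
#' @export
aliasFrequency <- function(f, sw) {
  if (length(sw) != 1L || !is.finite(sw) || sw <= 0)
    stop("sw must be a single finite value > 0")
  if (any(!is.finite(f)) || any(f < 0) || any(f >= sw))
    stop("f must lie in [0, sw)")
  ifelse(f <= sw / 2, f, sw - f)
}

#' Lorentzian full width at half maximum from the decay time
#'
#' A resonance decaying exponentially with time constant T2 has an
#' absorption-mode Lorentzian lineshape of full width at half maximum
#' 1 / (pi * T2).
#'
#' @param t2 decay time constant in seconds (> 0)
#' @return linewidth in Hz
#' @examples
#' linewidthFromT2(1 / pi)  # 1 Hz
#' @export
linewidthFromT2 <- function(t2) {
  if (any(!is.finite(t2)) || any(t2 <= 0))
    stop("t2 must be finite and > 0")
  1 / (pi * t2)
}

#' Decay time from a Lorentzian linewidth
#' @param lw full width at half maximum in Hz (> 0)
#' @return T2 in seconds
#' @export
t2FromLinewidth <- function(lw) {
  if (any(!is.finite(lw)) || any(lw <= 0))
    stop("lw must be finite and > 0")
  1 / (pi * lw)
}

#' Convert chemical shift in ppm to Hz
#'
#' A shift of x ppm at an observe frequency of F MHz is x * F Hz, since
#' 1 ppm of F * 1e6 Hz is F Hz.
#'
#' @param ppm chemical shift in ppm
#' @param spectrometerFreq observe frequency in MHz (> 0)
#' @return frequency in Hz
#' @examples
#' ppmToHz(7.5, 100)  # 750 Hz
#' @export
ppmToHz <- function(ppm, spectrometerFreq) {
  if (length(spectrometerFreq) != 1L || !is.finite(spectrometerFreq) ||
      spectrometerFreq <= 0)
    stop("spectrometerFreq must be a single finite value > 0")
  ppm * spectrometerFreq
}

#' Convert Hz to ppm
#' @param hz frequency in Hz
#' @param spectrometerFreq observe frequency in MHz (> 0)
#' @return chemical shift in ppm
#' @export
hzToPpm <- function(hz, spectrometerFreq) {
  if (length(spectrometerFreq) != 1L || !is.finite(spectrometerFreq) ||
      spectrometerFreq <= 0)
    stop("spectrometerFreq must be a single finite value > 0")
  hz / spectrometerFreq
}
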