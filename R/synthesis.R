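#' Build a validated table of Lorentzian peaks
#'
#' The package represents a resonance as four numbers: amplitude A (>= 0),
#' phase in radians, display frequency in Hz and decay time T2 in seconds.
#' Arguments are recycled to a common length.
#'
#' @param amplitude peak amplitudes, >= 0
#' @param frequency display frequencies in Hz
#' @param t2 decay times in seconds, > 0
#' @param phase phases in radians (default 0)
#' @return a data.frame with columns amplitude, phase, frequency, t2
#' @examples
#' peakTable(1, c(100, 300, 650, 750), 0.5)
#' @export
peakTable <- function(amplitude = numeric(), frequency = numeric(),
                      t2 = numeric(), phase = 0) {
  n <- max(length(amplitude), length(frequency), length(t2), length(phase),
           0L)
  if (length(frequency) == 0L) n <- 0L
  p <- data.frame(amplitude = rep_len(as.numeric(amplitude), n),
                  phase = rep_len(as.numeric(phase), n),
                  frequency = rep_len(as.numeric(frequency), n),
                  t2 = rep_len(as.numeric(t2), n))
  validatePeakTable(p)
  p
}

validatePeakTable <- function(peaks) {
  need <- c("amplitude", "phase", "frequency", "t2")
  if (!is.data.frame(peaks) || !all(need %in% names(peaks)))
    stop("peaks must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (nrow(peaks) == 0L) return(invisible(TRUE))
  if (any(!is.finite(peaks$amplitude)) || any(peaks$amplitude < 0))
    stop("peak amplitudes must be finite and >= 0")
  if (any(!is.finite(peaks$t2)) || any(peaks$t2 <= 0))
    stop("peak t2 values must be finite and > 0")
  if (any(!is.finite(peaks$phase)) || any(!is.finite(peaks$frequency)))
    stop("peak phases and frequencies must be finite")
  invisible(TRUE)
}

#' Synthesize an FID from a list of Lorentzian peaks
#'
#' Each point of the synthetic FID is the superposition of exponentially
#' decaying complex sinusoids,
#'   d_k = sum_j A_j exp(i Phi_j) exp(-k dt / tau_j) exp(2 pi i k dt w_j)
#'         + eps_k,
#' where dt is the dwell time, w_j the display frequency and tau_j the decay
#' time of peak j.  eps_k is optional complex white Gaussian noise with
#' standard deviation \code{noiseSd} per real component; with
#' \code{noiseSd = 0} the synthesis is exact and deterministic.
#'
#' Peak frequencies must lie on the display axis [0, SW): a frequency
#' outside that band would alias silently at synthesis time, so it is
#' rejected instead.
#'
#' @param peaks a peak table (see \code{\link{peakTable}}); may have 0 rows
#' @param params an \linkS4class{AcquisitionParams}
#' @param noiseSd standard deviation of the Gaussian noise added to each of
#'   the real and imaginary components (default 0: no noise)
#' @param seed integer seed for the noise generator; required when
#'   \code{noiseSd > 0} so synthesis is reproducible
#' @return an \linkS4class{FID} of \code{nPoints(params)} complex samples
#' @examples
#' p <- acquisitionParams(1000, 4096)
#' fid <- synthFid(peakTable(1, c(100, 300, 650, 750), 0.5), p)
#' @export
synthFid <- function(peaks, params, noiseSd = 0, seed = NULL) {
  validatePeakTable(peaks)
  validObject(params)
  if (length(noiseSd) != 1L || !is.finite(noiseSd) || noiseSd < 0)
    stop("noiseSd must be a single finite value >= 0")
  sw <- params@sw
  if (nrow(peaks) > 0L &&
      (any(peaks$frequency < 0) || any(peaks$frequency >= sw)))
    stop("peak frequencies must lie in [0, SW) = [0, ", sw,
         ") on the display axis")
  n <- params@nPoints
  dt <- params@dwell
  k <- seq_len(n) - 1
  d <- complex(real = rep(0, n), imaginary = rep(0, n))
  for (j in seq_len(nrow(peaks))) {
    d <- d + peaks$amplitude[j] * exp(1i * peaks$phase[j]) *
      exp(k * (complex(real = -dt / peaks$t2[j],
                       imaginary = 2 * pi * dt * peaks$frequency[j])))
  }
  if (noiseSd > 0) {
    if (is.null(seed))
      stop("a seed is required when noiseSd > 0")
    d <- d + withSeed(seed, complex(real = stats::rnorm(n, 0, noiseSd),
                                    imaginary = stats::rnorm(n, 0, noiseSd)))
  }
  newFid(d, params)
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' The four-peak aliasing demonstration fixture
#'
#' A simulated spectrum with a spectral width of 1000 Hz containing four
#' equal-amplitude resonances at 100, 300, 650 and 750 Hz: the worked
#' example for the aliasing demonstration.  Played back from the real part
#' alone, the two resonances above the 500 Hz Nyquist frequency fold to 250
#' and 350 Hz; through the ZPFD path all four are heard at their true
#' frequencies.  Unit amplitudes, zero phases, T2 = 0.5 s (linewidth about
#' 0.64 Hz), N = 4096 points, no noise.
#'
#' @return a list with elements \code{fid} (\linkS4class{FID}),
#'   \code{params} (\linkS4class{AcquisitionParams}) and \code{peaks}
#'   (the peak table used)
#' @examples
#' fx <- fourPeakFixture()
#' sweepWidth(fx$fid)
#' @export
fourPeakFixture <- function() {
  params <- acquisitionParams(sw = 1000, nPoints = 4096)
  peaks <- peakTable(amplitude = 1, frequency = c(100, 300, 650, 750),
                     t2 = 0.5)
  list(fid = synthFid(peaks, params), params = params, peaks = peaks)
}

#' Build a validated table of spectral regions of interest
#'
#' @param label region labels (free text, e.g. "aromatic")
#' @param fLow lower display-frequency bounds in Hz
#' @param fHigh upper bounds in Hz (each > the matching fLow)
#' @return a data.frame with columns label, fLow, fHigh
#' @export
regionTable <- function(label = character(), fLow = numeric(),
                        fHigh = numeric()) {
  r <- data.frame(label = as.character(label), fLow = as.numeric(fLow),
                  fHigh = as.numeric(fHigh))
  validateRegionTable(r)
  r
}

validateRegionTable <- function(regions, requireDisjoint = FALSE) {
  need <- c("label", "fLow", "fHigh")
  if (!is.data.frame(regions) || !all(need %in% names(regions)))
    stop("regions must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (nrow(regions) == 0L) return(invisible(TRUE))
  if (any(!is.finite(regions$fLow)) || any(!is.finite(regions$fHigh)) ||
      any(regions$fLow >= regions$fHigh))
    stop("each region must satisfy fLow < fHigh with finite bounds")
  if (requireDisjoint && nrow(regions) > 1L) {
    o <- order(regions$fLow)
    if (any(regions$fHigh[o][-nrow(regions)] > regions$fLow[o][-1]))
      stop("regions must be pairwise non-overlapping")
  }
  invisible(TRUE)
}

#' A synthetic three-region proton-like fixture
#'
#' An FID carrying small peak clusters in the three zones a chemist listens
#' for: aliphatic (1-3 ppm), olefinic (5-6 ppm) and aromatic (7-8 ppm),
#' converted to display Hz at the given observe frequency, together with
#' the matching region table.  The multiplet content is a documented
#' synthetic choice, not the spectrum of any real compound; it exists so
#' the region-wise audification pipeline can be exercised end to end
#' without instrument data.
#'
#' @param spectrometerFreq observe frequency in MHz (default 100, giving a
#'   0-10 ppm axis over SW = 1000 Hz)
#' @return a list with elements \code{fid}, \code{regions}, \code{peaks}
#'   and \code{params}
#' @examples
#' fx <- threeRegionFixture()
#' fx$regions
#' @export
threeRegionFixture <- function(spectrometerFreq = 100) {
  if (length(spectrometerFreq) != 1L || !is.finite(spectrometerFreq) ||
      spectrometerFreq <= 0)
    stop("spectrometerFreq must be a single finite value > 0")
  sw <- ppmToHz(10, spectrometerFreq)  # 0-10 ppm window
  params <- acquisitionParams(sw = sw, nPoints = 4096,
                              spectrometerFreq = spectrometerFreq)
  shifts <- c(1.6, 1.7, 2.4,       # aliphatic cluster
              5.4, 5.5,            # olefinic pair
              7.2, 7.3, 7.4)       # aromatic cluster
  amps <- c(1.0, 1.0, 1.5, 0.8, 0.8, 1.0, 1.2, 1.0)
  peaks <- peakTable(amplitude = amps,
                     frequency = ppmToHz(shifts, spectrometerFreq),
                     t2 = 0.4)
  regions <- regionTable(
    label = c("aliphatic", "olefinic", "aromatic"),
    fLow = ppmToHz(c(1, 5, 7), spectrometerFreq),
    fHigh = ppmToHz(c(3, 6, 8), spectrometerFreq))
  list(fid = synthFid(peaks, params), regions = regions, peaks = peaks,
       params = params)
}
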