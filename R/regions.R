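#' Deconvolve a spectrum into Lorentzian peaks
#'
#' A simple peak picker standing in for full spectral deconvolution:
#' (1) the noise floor is estimated robustly as the scaled median absolute
#' deviation of the magnitude spectrum (peaks are sparse, so the median
#' sits on the peak-free context); (2) local maxima of the magnitude above
#' \code{noiseK} times that floor are located, within the given regions or
#' everywhere; (3) each maximum is refined by least-squares fitting of the
#' magnitude profile of a complex Lorentzian,
#' |A / (1/tau + 2 pi i (f - w))| / dt, over a window of +/- 5 bins,
#' yielding a sub-bin frequency, an amplitude on the synthesis scale and a
#' decay time t2 = tau.  Phases are set to zero.  If a fit fails to
#' converge the peak falls back to the grid maximum and its half-height
#' width (with a message).
#'
#' @param spectrum a \linkS4class{Spectrum}
#' @param regions optional region table (see \code{\link{regionTable}});
#'   when given, only maxima inside a region are kept
#' @param noiseK detection threshold as a multiple of the noise floor
#'   (default 5)
#' @return a peak table (columns amplitude, phase, frequency, t2) sorted by
#'   frequency; zero rows when nothing exceeds the threshold
#' @examples
#' fx <- fourPeakFixture()
#' pickPeaks(fourierTransform(fx$fid))$frequency
#' @export
pickPeaks <- function(spectrum, regions = NULL, noiseK = 5) {
  stopifnot(is(spectrum, "Spectrum"))
  if (length(noiseK) != 1L || !is.finite(noiseK) || noiseK <= 0)
    stop("noiseK must be a single finite value > 0")
  if (!is.null(regions)) validateRegionTable(regions)
  mag <- Mod(spectrum@values)
  n <- length(mag)
  freq <- spectrum@axis
  sw <- spectrum@params@sw
  step <- sw / n
  top <- max(mag)
  if (top == 0) return(peakTable())
  sigma <- stats::mad(mag)
  thr <- max(noiseK * sigma, 1e-9 * top)
  # the DFT is circulant: a line near one band edge continues across the
  # other, so maxima are located with wrapped neighbours
  left <- mag[c(n, seq_len(n - 1))]
  right <- mag[c(seq_len(n - 1) + 1L, 1L)]
  idx <- which(mag > left & mag >= right & mag >= thr)
  if (!is.null(regions) && length(idx)) {
    inside <- vapply(freq[idx], function(f)
      any(f >= regions$fLow & f < regions$fHigh), logical(1))
    idx <- idx[inside]
  }
  if (length(idx) == 0L) return(peakTable())
  # collapse plateau duplicates within 2 bins, keeping the larger
  idx <- idx[order(idx)]
  keep <- integer(); cur <- idx[1]
  for (i in idx[-1]) {
    if (i - cur <= 2L) { if (mag[i] > mag[cur]) cur <- i }
    else { keep <- c(keep, cur); cur <- i }
  }
  idx <- c(keep, cur)

  out <- lapply(idx, function(i)
    fitLorentzianPeak(mag, freq, i, step, sw, spectrum@params@dwell))
  out <- do.call(rbind, out)
  out <- out[order(out$frequency), , drop = FALSE]
  rownames(out) <- NULL
  validatePeakTable(out)
  out
}

## Least-squares refinement of one magnitude-spectrum maximum.
## Model: the DFT magnitude of a unit-step-sampled exponential decay,
## approximated by the continuous-FT magnitude A*tau/dt / sqrt(1 + (2 pi
## (f - w) tau)^2).  The fit window wraps across the band edges (the DFT is
## circulant) using a local unwrapped frequency coordinate.  Returns a
## 1-row peak table.
fitLorentzianPeak <- function(mag, freq, i, step, sw, dt) {
  n <- length(mag)
  h <- min(5L, (n - 1L) %/% 2L)
  off <- -h:h
  magW <- mag[(i - 1L + off) %% n + 1L]
  fW <- freq[i] + off * step
  ctr <- h + 1L
  height <- magW[ctr]
  f0 <- fW[ctr]
  # half-height width estimate for starting values (magnitude profile of a
  # complex Lorentzian has full width sqrt(3)/(pi*tau) at half height)
  halfw <- function(side) {
    js <- if (side < 0) (ctr - 1L):1L else (ctr + 1L):length(off)
    for (j in js) {
      if (magW[j] <= height / 2) {
        prev <- j - side
        frac <- (magW[prev] - height / 2) / (magW[prev] - magW[j])
        return(abs(fW[prev] + side * frac * step - f0))
      }
    }
    abs(fW[if (side < 0) 1L else length(off)] - f0)
  }
  fwhm <- max(halfw(-1) + halfw(1), step / 2)
  tau0 <- sqrt(3) / (pi * fwhm)
  a0 <- height * dt / tau0
  dat <- data.frame(f = fW, m = magW)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      m ~ (a * tau / dt) / sqrt(1 + (2 * pi * (f - w) * tau)^2),
      data = dat,
      start = list(a = a0, w = f0, tau = tau0),
      lower = c(0, f0 - h * step, tau0 / 100),
      upper = c(Inf, f0 + h * step, tau0 * 100),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  ok <- !is.null(fit)
  if (ok) {
    cf <- stats::coef(fit)
    ok <- is.finite(cf[["a"]]) && is.finite(cf[["w"]]) &&
      is.finite(cf[["tau"]]) && cf[["tau"]] > 0 &&
      cf[["w"]] >= f0 - h * step && cf[["w"]] <= f0 + h * step
  }
  if (!ok) {
    message(sprintf(
      "peak fit did not converge near %.2f Hz; using grid estimate", f0))
    return(peakTable(amplitude = a0, frequency = f0 %% sw, t2 = tau0))
  }
  peakTable(amplitude = cf[["a"]], frequency = cf[["w"]] %% sw,
            t2 = cf[["tau"]])
}

#' Synthesize the sub-FID of one spectral region
#'
#' Rebuilds the time-domain signal of a single region of interest from
#' picked peaks, assuming pure exponential (Lorentzian) decays: only peaks
#' with fLow <= frequency < fHigh contribute, phases are set to zero and no
#' noise is added.  Frequencies stay on the absolute display axis, so the
#' region's pitch in audio equals its position in the spectrum.
#'
#' @param peaks a peak table (any frequencies; filtered here)
#' @param region a 1-row region table (or list with fLow, fHigh)
#' @param params the \linkS4class{AcquisitionParams} to synthesize under
#' @return an \linkS4class{FID}; all-zero when the region holds no peaks
#' @export
synthSubfid <- function(peaks, region, params) {
  validatePeakTable(peaks)
  if (is.data.frame(region)) {
    if (nrow(region) != 1L) stop("region must be a single region")
    validateRegionTable(region)
  }
  sel <- peaks$frequency >= region$fLow & peaks$frequency < region$fHigh
  sub <- peaks[sel, , drop = FALSE]
  sub$phase <- rep(0, nrow(sub))
  synthFid(sub, params, noiseSd = 0)
}

#' Audify a spectrum region by region
#'
#' The acoustic-mapping pipeline for structure interpretation: the spectrum
#' is deconvolved into peaks; for each region of interest, taken from right
#' (high field, low display frequency) to left, a sub-FID is resynthesized
#' from the in-region peaks and rendered through the alias-free ZPFD path;
#' the resulting segments are trimmed to a common duration, tapered at both
#' ends with a 10 ms raised cosine, and concatenated with a silent gap
#' between them.  A region without peaks contributes a silent segment of
#' the same duration so segment position keeps its meaning.  One
#' normalization pass is applied to the concatenated result, preserving
#' relative intensities between regions.
#'
#' @param spectrum a \linkS4class{Spectrum}
#' @param regions a non-empty, pairwise non-overlapping region table
#' @param segmentS duration of each segment in seconds; default
#'   min(acquisition time, 5 * the largest picked in-region t2)
#' @param gapS silent gap between segments in seconds (default 0.2)
#' @param noiseK peak-detection threshold passed to \code{\link{pickPeaks}}
#' @param taperS raised-cosine edge taper length in seconds (default 0.01)
#' @param headroom peak amplitude of the final normalization (default 0.9)
#' @return an \linkS4class{AudioSignal} at rate round(2 * SW), with a
#'   \code{"segments"} attribute: a data.frame of label, startSample,
#'   nSamples and nPeaks per segment in playback order
#' @examples
#' fx <- threeRegionFixture()
#' a <- regionAudify(fourierTransform(fx$fid), fx$regions)
#' attr(a, "segments")
#' @export
regionAudify <- function(spectrum, regions, segmentS = NULL, gapS = 0.2,
                         noiseK = 5, taperS = 0.01, headroom = 0.9) {
  stopifnot(is(spectrum, "Spectrum"))
  validateRegionTable(regions, requireDisjoint = TRUE)
  if (nrow(regions) == 0L) stop("at least one region is required")
  if (length(gapS) != 1L || !is.finite(gapS) || gapS < 0)
    stop("gapS must be a single finite value >= 0")
  regions <- regions[order(regions$fLow), , drop = FALSE]
  params <- spectrum@params
  rate <- as.integer(round(2 * params@sw))
  peaks <- pickPeaks(spectrum, regions, noiseK)
  if (is.null(segmentS)) {
    acqT <- params@nPoints * params@dwell
    segmentS <- if (nrow(peaks)) min(acqT, 5 * max(peaks$t2)) else acqT
  }
  if (length(segmentS) != 1L || !is.finite(segmentS) || segmentS <= 0)
    stop("segmentS must be a single finite value > 0")
  segN <- max(1L, as.integer(round(segmentS * rate)))
  gapN <- as.integer(round(gapS * rate))

  segs <- vector("list", nrow(regions))
  meta <- data.frame(label = regions$label, startSample = NA_integer_,
                     nSamples = segN, nPeaks = 0L)
  for (r in seq_len(nrow(regions))) {
    inReg <- peaks$frequency >= regions$fLow[r] &
      peaks$frequency < regions$fHigh[r]
    meta$nPeaks[r] <- sum(inReg)
    if (!any(inReg)) {
      message(sprintf("region '%s' has no peaks; emitting silence",
                      regions$label[r]))
      segs[[r]] <- rep(0, segN)
      next
    }
    sub <- synthSubfid(peaks, regions[r, , drop = FALSE], params)
    a <- zpfdAudify(fourierTransform(sub))
    s <- a@samples
    s <- if (length(s) >= segN) s[seq_len(segN)]
         else c(s, rep(0, segN - length(s)))
    segs[[r]] <- applyEdgeTaper(s, rate, taperS)
  }
  gap <- rep(0, gapN)
  out <- segs[[1]]
  if (nrow(regions) > 1L)
    for (r in 2:nrow(regions)) out <- c(out, gap, segs[[r]])
  meta$startSample <- (seq_len(nrow(regions)) - 1L) * (segN + gapN)
  audio <- normalizeQuantize(audioSignal(out, rate), headroom)
  attr(audio, "segments") <- meta
  audio
}

## Raised-cosine (half-Hann) ramps over the first and last `taperS` seconds.
applyEdgeTaper <- function(s, rate, taperS) {
  nt <- min(as.integer(round(taperS * rate)), floor(length(s) / 2))
  if (nt < 1L) return(s)
  ramp <- 0.5 * (1 - cos(pi * (seq_len(nt) - 0.5) / nt))
  s[seq_len(nt)] <- s[seq_len(nt)] * ramp
  tail <- length(s) - nt + seq_len(nt)
  s[tail] <- s[tail] * rev(ramp)
  s
}
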