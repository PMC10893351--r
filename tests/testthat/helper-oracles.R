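# Independent oracles and small generators shared across the suite.

# Brute-force DFT (quadratic sum), independent of stats::fft.
directDft <- function(x, inverse = FALSE) {
  n <- length(x)
  sgn <- if (inverse) 1i else -1i
  vapply(seq_len(n) - 1, function(m)
    sum(x * exp(sgn * 2 * pi * (seq_len(n) - 1) * m / n)),
    complex(1))
}

# Full width at half maximum of a profile sampled on a uniform grid,
# with linear interpolation at the half-height crossings.
gridFwhm <- function(freq, y) {
  i <- which.max(y)
  h <- y[i] / 2
  li <- max(which(y[seq_len(i)] <= h))
  fl <- freq[li] + (freq[li + 1] - freq[li]) * (h - y[li]) / (y[li + 1] - y[li])
  ri <- i - 1 + min(which(y[i:length(y)] <= h))
  fr <- freq[ri - 1] +
    (freq[ri] - freq[ri - 1]) * (y[ri - 1] - h) / (y[ri - 1] - y[ri])
  fr - fl
}

# Random well-separated peak list on [margin, sw - margin], minimum
# spacing sepHz, for recovery and anti-aliasing property tests.
randomPeaks <- function(nPeaks, sw, sepHz = 8, margin = 10) {
  repeat {
    f <- sort(runif(nPeaks, margin, sw - margin))
    if (nPeaks == 1L || min(diff(f)) >= sepHz) break
  }
  peakTable(amplitude = runif(nPeaks, 0.5, 1.5), frequency = f,
            t2 = runif(nPeaks, 0.3, 0.8))
}

expect_setequal_hz <- function(found, truth, tol) {
  expect_equal(length(found), length(truth))
  expect_true(all(abs(sort(found) - sort(truth)) < tol))
}
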