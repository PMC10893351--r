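test_that("the picker recovers a single Lorentzian's parameters sub-bin", {
  p <- acquisitionParams(1000, 4096)
  s <- fourierTransform(synthFid(peakTable(1, 400, 0.5), p))
  pk <- pickPeaks(s)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$frequency - 400), 1000 / (2 * 4096))
  expect_lt(abs(pk$amplitude - 1), 0.1)
  expect_lt(abs(pk$t2 - 0.5), 0.05)
  expect_equal(pk$phase, 0)
})

test_that("an all-zero spectrum yields an empty peak list", {
  p <- acquisitionParams(1000, 256)
  expect_equal(nrow(pickPeaks(newSpectrum(rep(0 + 0i, 256), p))), 0L)
})

test_that("region filtering keeps only in-region maxima", {
  fx <- fourPeakFixture()
  s <- fourierTransform(fx$fid)
  low <- regionTable("low", 0, 500)
  pk <- pickPeaks(s, low)
  expect_setequal_hz(pk$frequency, c(100, 300), 1000 / 4096)
})

test_that("sub-FID synthesis uses only in-region peaks, phase 0, no noise", {
  p <- acquisitionParams(1000, 1024)
  peaks <- peakTable(amplitude = c(1, 2), frequency = c(200, 700),
                     t2 = 0.4, phase = c(0.3, -0.2))
  lowR <- regionTable("low", 0, 500)
  highR <- regionTable("high", 500, 1000)
  sub <- synthSubfid(peaks, lowR, p)
  det <- analyzeAudio(zpfdAudify(fourierTransform(sub)))
  expect_equal(det$frequency[which.max(det$magnitude)], 200,
               tolerance = 1000 / 1024)
  empty <- synthSubfid(peaks, regionTable("void", 400, 500), p)
  expect_equal(samples(empty), rep(0 + 0i, 1024))
  # a partition of the axis reconstructs the phase-zero full synthesis
  zeroPhase <- peaks; zeroPhase$phase <- 0
  expect_equal(samples(synthSubfid(peaks, lowR, p)) +
                 samples(synthSubfid(peaks, highR, p)),
               samples(synthFid(zeroPhase, p)), tolerance = 1e-12)
})

test_that("region audio plays segments in ascending frequency with exact gaps", {
  fx <- threeRegionFixture()
  s <- fourierTransform(fx$fid)
  a <- regionAudify(s, fx$regions, gapS = 0.2)
  segs <- attr(a, "segments")
  expect_equal(segs$label, c("aliphatic", "olefinic", "aromatic"))
  expect_true(all(diff(segs$startSample) > 0))
  rate <- sampleRate(a)
  gapN <- round(0.2 * rate)
  expect_equal(length(samples(a)), 3 * segs$nSamples[1] + 2 * gapN)
  expect_equal(max(abs(samples(a))), 0.9)        # one global normalization
  # every segment's detected frequencies lie inside its own region
  r <- fx$regions[order(fx$regions$fLow), ]
  binHz <- sweepWidth(s) / nPoints(s)
  allFound <- numeric()
  for (i in 1:3) {
    seg <- samples(a)[segs$startSample[i] + seq_len(segs$nSamples[i])]
    det <- analyzeAudio(audioSignal(seg, rate))
    expect_true(all(det$frequency >= r$fLow[i] - binHz &
                    det$frequency < r$fHigh[i] + binHz))
    expect_gt(sqrt(mean(seg^2)), 1e-4)           # non-silent segment
    allFound <- c(allFound, det$frequency)
  }
  # pipeline recovery: the multiset across segments is the input peak set
  tol <- 2000 / segs$nSamples[1]                 # segment analyzer resolution
  expect_setequal_hz(allFound, fx$peaks$frequency, tol + binHz)
})

test_that("a single whole-axis region degenerates to global ZPFD audification", {
  fx <- fourPeakFixture()
  s <- fourierTransform(fx$fid)
  a <- regionAudify(s, regionTable("all", 0, 1000), taperS = 0)
  whole <- analyzeAudio(zpfdAudify(s))
  det <- analyzeAudio(audioSignal(samples(a), sampleRate(a)))
  expect_setequal_hz(det$frequency, whole$frequency, 1000 / 4096)
})

test_that("peak-free regions produce silent same-length segments, with notice", {
  fx <- fourPeakFixture()
  s <- fourierTransform(fx$fid)
  regions <- regionTable(c("low", "void", "high"),
                         c(0, 410, 600), c(400, 590, 1000))
  expect_message(a <- regionAudify(s, regions), "no peaks")
  segs <- attr(a, "segments")
  expect_equal(segs$nPeaks, c(2L, 0L, 2L))
  mid <- samples(a)[segs$startSample[2] + seq_len(segs$nSamples[2])]
  expect_equal(mid, rep(0, segs$nSamples[2]))
  expect_equal(segs$nSamples[2], segs$nSamples[1])
})

test_that("zero or overlapping regions are refused", {
  fx <- fourPeakFixture()
  s <- fourierTransform(fx$fid)
  expect_error(regionAudify(s, regionTable()), "at least one region")
  bad <- regionTable(c("a", "b"), c(0, 300), c(400, 700))
  expect_error(regionAudify(s, bad), "non-overlapping")
})

test_that("segment edges follow the raised-cosine taper envelope", {
  taper <- nmraudify:::applyEdgeTaper
  n <- 200L; rate <- 1000L                       # 10 ms -> 10 samples
  out <- taper(rep(1, n), rate, 0.01)
  ramp <- 0.5 * (1 - cos(pi * (1:10 - 0.5) / 10))
  expect_equal(out[1:10], ramp)
  expect_equal(out[191:200], rev(ramp))
  expect_equal(out[11:190], rep(1, 180))
  expect_true(all(out <= 1))
})
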