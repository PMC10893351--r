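binHz1000 <- 1000 / 4096

test_that("real-part playback folds high frequencies; ZPFD does not", {
  fx <- fourPeakFixture()
  naive <- analyzeAudio(realAudify(fx$fid))
  expect_setequal_hz(naive$frequency, c(100, 250, 300, 350), binHz1000)
  zp <- analyzeAudio(zpfdAudify(fourierTransform(fx$fid)))
  expect_setequal_hz(zp$frequency, c(100, 300, 650, 750), binHz1000)
})

test_that("single peaks land at the folding-law frequency in real audio", {
  p <- acquisitionParams(1000, 4096)
  for (f0 in c(200, 900, 510, 499)) {
    fid <- synthFid(peakTable(1, f0, 0.5), p)
    det <- analyzeAudio(realAudify(fid))
    expect_equal(det$frequency[which.max(det$magnitude)],
                 aliasFrequency(f0, 1000), tolerance = binHz1000)
  }
})

test_that("ZPFD doubles points, halves nothing: duration is preserved", {
  fx <- fourPeakFixture()
  s <- fourierTransform(fx$fid)
  a <- zpfdAudify(s)
  expect_equal(length(samples(a)), 2L * nPoints(s))
  expect_equal(sampleRate(a), 2000L)
  expect_equal(duration(a), duration(fx$fid))  # 2N / (2 SW) = N dt
})

test_that("ZPFD is alias-free even at the extreme band edge", {
  # t2 = 5 s keeps the line's circulant tail (which genuinely wraps past
  # the band edge) below the detection threshold, so anything seen near
  # 1 Hz could only be a fold-back artefact
  p <- acquisitionParams(1000, 4096)
  fid <- synthFid(peakTable(1, 999, 5), p)
  det <- analyzeAudio(zpfdAudify(fourierTransform(fid)))
  expect_equal(det$frequency[which.max(det$magnitude)], 999,
               tolerance = binHz1000)
  expect_false(any(det$frequency < 5))         # no fold-back near 1 Hz
})

test_that("ZPFD of silence is silence, and the op is linear pre-normalization", {
  p <- acquisitionParams(1000, 64)
  zero <- newSpectrum(rep(0 + 0i, 64), p)
  expect_equal(samples(zpfdAudify(zero)), rep(0, 128))
  set.seed(8)
  s1 <- newSpectrum(complex(real = rnorm(64), imaginary = rnorm(64)), p)
  s2 <- newSpectrum(complex(real = rnorm(64), imaginary = rnorm(64)), p)
  s12 <- newSpectrum(specValues(s1) + specValues(s2), p)
  expect_equal(samples(zpfdAudify(s12)),
               samples(zpfdAudify(s1)) + samples(zpfdAudify(s2)),
               tolerance = 1e-12)
})

test_that("anti-aliasing holds over random peak lists", {
  # the module's core contract: detected == input frequencies, no aliases
  set.seed(101)
  p <- acquisitionParams(1000, 4096)
  for (trial in 1:20) {
    truth <- randomPeaks(sample(1:10, 1), 1000)
    det <- analyzeAudio(zpfdAudify(fourierTransform(synthFid(truth, p))))
    expect_setequal_hz(det$frequency, truth$frequency, binHz1000)
  }
})

test_that("normalization scales to the headroom and passes silence through", {
  a <- audioSignal(c(0.5, -0.25), 48000)
  expect_equal(samples(normalizeQuantize(a)), c(0.9, -0.45))
  z <- audioSignal(rep(0, 10), 1000)
  expect_identical(samples(normalizeQuantize(z)), rep(0, 10))
  set.seed(9)
  r <- audioSignal(rnorm(100), 1000)
  expect_equal(max(abs(samples(normalizeQuantize(r, 0.7)))), 0.7)
  expect_error(normalizeQuantize(a, 0), "headroom")
  expect_error(normalizeQuantize(a, 1.5), "headroom")
})

test_that("the analyzer resolves a pure decaying tone and ignores silence", {
  t <- (0:8191) / 2000
  tone <- audioSignal(cos(2 * pi * 440 * t) * exp(-t / 0.5), 2000)
  det <- analyzeAudio(tone)
  expect_equal(nrow(det), 1L)
  expect_equal(det$frequency, 440, tolerance = 2000 / 8192)
  expect_equal(det$magnitude, 1)
  silent <- audioSignal(rep(0, 64), 1000)
  expect_equal(nrow(analyzeAudio(silent)), 0L)
})

test_that("WAV round trip is within one quantization step, bit-stable, 2xSW", {
  fx <- fourPeakFixture()
  audio <- normalizeQuantize(zpfdAudify(fourierTransform(fx$fid)))
  wav <- withr::local_tempfile(fileext = ".wav")
  writeWav(audio, wav)
  back <- readWav(wav)
  expect_equal(sampleRate(back), 2000L)
  expect_lt(max(abs(samples(back) - samples(audio))), 1 / 32768)
  # header sample-rate field, bytes 25-28 little-endian
  hdr <- readBin(wav, "raw", 44)
  expect_equal(readBin(hdr[25:28], "integer", size = 4, endian = "little"),
               2000L)
  expect_equal(rawToChar(hdr[1:4]), "RIFF")
  wav2 <- withr::local_tempfile(fileext = ".wav")
  writeWav(audio, wav2)
  expect_identical(readBin(wav, "raw", file.size(wav)),
                   readBin(wav2, "raw", file.size(wav2)))
})

test_that("unnormalized or empty audio is refused by the WAV writer", {
  expect_error(writeWav(audioSignal(numeric(), 1000),
                        tempfile(fileext = ".wav")), "empty")
  loud <- audioSignal(c(0, 1.5), 1000)
  expect_error(writeWav(loud, tempfile(fileext = ".wav")), "normalized")
})
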