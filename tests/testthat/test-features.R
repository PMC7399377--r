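# Feature extraction: closed-form spectrum oracles on pure tones and
# noise, the independent MFCC reference, HF500 band arithmetic, and the
# scaling/concatenation invariants.

test_that("silent frames map to defined finite values", {
  rec <- audioRecording(rep(0, 16000), 16000L, "zero")
  fm <- featurizeRecording(rec, frameGrid(rec))
  vals <- featureValues(fm)
  expect_true(all(is.finite(vals)))
  expect_true(all(vals[, "energy"] == 0))
  expect_true(all(vals[, "zero_crossing_rate"] == 0))
  expect_true(all(vals[, "hf500"] == 0))
  expect_true(all(vals[, "harmonic_ratio"] == 0))
  expect_true(all(vals[, "f0"] == 0))
})

test_that("a pure tone puts the centroid and f0 at its frequency", {
  rec <- sineRecording(1000, 1.0, fs = 16000L)
  vals <- featureValues(featurizeRecording(rec, frameGrid(rec)))
  binHz <- 16000 / 1600
  expect_true(all(abs(vals[, "spectral_centroid"] - 1000) <= binHz))
  expect_true(all(abs(vals[, "f0"] - 1000) / 1000 <= 0.05))
  expect_true(all(vals[, "harmonic_ratio"] > 0.9))
})

test_that("white noise is spectrally flat and inharmonic", {
  set.seed(7)
  rec <- audioRecording(rnorm(32000, 0, 0.1), 16000L, "noise")
  vals <- featureValues(featurizeRecording(rec, frameGrid(rec)))
  # flat spectrum: normalized entropy near its maximum of 1
  expect_true(mean(vals[, "spectral_entropy"]) > 0.9)
  expect_true(all(vals[, "harmonic_ratio"] < 0.3))
})

test_that("a 440 Hz tone concentrates chroma mass in pitch class A", {
  rec <- sineRecording(440, 0.5, fs = 16000L)
  vals <- featureValues(featurizeRecording(rec, frameGrid(rec)))
  expect_true(all(vals[, "chroma_1"] > 0.8)) # class 1 = A at the 440 reference
  ps <- framePowerSpectrum(samples(rec)[1:1600])
  ch <- computeChroma(ps, 16000)
  expect_gt(ch[1], 0.8)
  expect_equal(sum(ch), 1, tolerance = 1e-9)
})

test_that("MFCCs match an independent filterbank + DCT reference", {
  fs <- 16000
  ps <- framePowerSpectrum(0.4 * sin(2 * pi * 1000 * (0:1599) / fs))

  # independent reference: Slaney mel filterbank and orthonormal DCT-II,
  # computed with explicit loops straight from the definitions
  hz2mel <- function(f) if (f < 1000) f * 3 / 200 else 15 + 27 * log(f / 1000) / log(6.4)
  mel2hz <- function(m) if (m < 15) m * 200 / 3 else 1000 * 6.4^((m - 15) / 27)
  nFil <- 40L
  nBins <- length(ps)
  edges <- vapply(
    seq(hz2mel(0), hz2mel(fs / 2), length.out = nFil + 2), mel2hz, numeric(1)
  )
  freqs <- (0:(nBins - 1)) * fs / 1600
  melE <- numeric(nFil)
  for (m in 1:nFil) {
    acc <- 0
    for (k in 1:nBins) {
      f <- freqs[k]
      w <- 0
      if (f >= edges[m] && f <= edges[m + 1]) {
        w <- (f - edges[m]) / (edges[m + 1] - edges[m])
      } else if (f > edges[m + 1] && f <= edges[m + 2]) {
        w <- (edges[m + 2] - f) / (edges[m + 2] - edges[m + 1])
      }
      acc <- acc + w * 2 / (edges[m + 2] - edges[m]) * ps[k]
    }
    melE[m] <- acc
  }
  ref <- numeric(13)
  for (k in 0:12) {
    s <- 0
    for (j in 1:nFil) {
      s <- s + log(max(melE[j], 1e-10)) * cos(pi * k * (2 * j - 1) / (2 * nFil))
    }
    ref[k + 1] <- s * if (k == 0) sqrt(1 / nFil) else sqrt(2 / nFil)
  }

  got <- computeMfcc(ps, fs)
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("scaling the spectrum shifts only the first cepstral coefficient", {
  set.seed(11)
  ps <- abs(rnorm(801))^2 + 0.1
  base <- computeMfcc(ps, 16000)
  scaled <- computeMfcc(7 * ps, 16000)
  d <- scaled - base
  expect_equal(d[1], sqrt(40) * log(7), tolerance = 1e-9)
  expect_true(all(abs(d[-1]) < 1e-9))
})

test_that("HF500 band arithmetic", {
  fs <- 16000
  nBins <- 801 # 1600-point DFT
  freqs <- (0:(nBins - 1)) * fs / 1600

  lowTone <- framePowerSpectrum(sin(2 * pi * 200 * (0:1599) / fs))
  expect_lt(computeHf500(lowTone, fs), 0.01)

  highTone <- framePowerSpectrum(sin(2 * pi * 1000 * (0:1599) / fs))
  expect_gt(computeHf500(highTone, fs), 1e6) # denominator at its floor

  # equal power in one 300 Hz bin and one 2000 Hz bin -> exactly 1
  ps <- numeric(nBins)
  ps[which(freqs == 300)] <- 5
  ps[which(freqs == 2000)] <- 5
  expect_identical(computeHf500(ps, fs), 1)

  expect_error(computeHf500(ps, 6000), class = "dyadiar_validation_error")
})

test_that("gain scaling leaves ratio/shape features unchanged, energy x c^2", {
  d <- buildDialogue(
    voiceSpec(110), voiceSpec(210),
    dialogueSpec(durationS = 12, seed = 9)
  )
  rec <- d@recording
  grid <- frameGrid(rec)
  rec2 <- audioRecording(samples(rec) * 2, sampleRate(rec), "x2")
  a <- featureValues(featurizeRecording(rec, grid))
  b <- featureValues(featurizeRecording(rec2, grid))
  invariant <- c(
    "zero_crossing_rate", "spectral_centroid", "spectral_entropy",
    "spectral_rolloff", paste0("chroma_", 1:12), "harmonic_ratio",
    "f0", "hf500"
  )
  for (f in invariant) {
    expect_equal(b[, f], a[, f], tolerance = 1e-6, label = f)
  }
  expect_equal(b[, "energy"], 4 * a[, "energy"], tolerance = 1e-9)
})

test_that("featurization is frame-local except spectral flux at the seam", {
  set.seed(3)
  x1 <- rnorm(8000, 0, 0.1)
  x2 <- 0.3 * sin(2 * pi * 330 * (0:7999) / 16000)
  r1 <- audioRecording(x1, 16000L, "a")
  r2 <- audioRecording(x2, 16000L, "b")
  rc <- audioRecording(c(x1, x2), 16000L, "ab")
  fa <- featureValues(featurizeRecording(r1, frameGrid(r1)))
  fb <- featureValues(featurizeRecording(r2, frameGrid(r2)))
  fc <- featureValues(featurizeRecording(rc, frameGrid(rc)))
  stacked <- rbind(fa, fb)
  seam <- nrow(fa) + 1L
  notFlux <- setdiff(colnames(fc), "spectral_flux")
  expect_equal(fc[, notFlux], stacked[, notFlux], tolerance = 1e-9)
  expect_equal(fc[-seam, "spectral_flux"], stacked[-seam, "spectral_flux"],
    tolerance = 1e-9)
})

test_that("pitch primitives handle tones, noise and degenerate frames", {
  fs <- 16000
  tone <- 0.5 * sin(2 * pi * 440 * (0:1599) / fs)
  expect_equal(computeF0(tone, fs), 440, tolerance = 0.05 * 440)
  expect_gt(computeHarmonicRatio(tone, fs), 0.9)
  set.seed(5)
  expect_lt(computeHarmonicRatio(rnorm(1600), fs), 0.3)
  expect_identical(computeF0(rep(0, 1600), fs), 0)
  expect_identical(computeHarmonicRatio(rep(0, 1600), fs), 0)
})
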