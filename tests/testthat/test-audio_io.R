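# Audio and label artifact I/O, frame grid arithmetic, and the
# annotation <-> stream conversions.

test_that("WAV round trip preserves samples within quantization", {
  rec <- sineRecording(440, 0.5, fs = 44100L, amp = 0.8)
  path <- withr::local_tempfile(fileext = ".wav")
  writeWav(rec, path)
  back <- readWav(path)
  expect_equal(sampleRate(back), 44100L)
  expect_equal(length(samples(back)), length(samples(rec)))
  expect_lt(max(abs(samples(back) - samples(rec))), 1 / 32768)

  # 2 s mono at 16 kHz -> 32000 samples
  rec2 <- sineRecording(100, 2, fs = 16000L)
  writeWav(rec2, path)
  expect_equal(length(samples(readWav(path))), 32000L)
})

test_that("stereo input with identical channels reads as that channel", {
  fs <- 16000L
  x <- round(0.3 * sin(2 * pi * 220 * (0:7999) / fs) * 32767)
  path <- withr::local_tempfile(fileext = ".wav")
  con <- file(path, "wb")
  dataSize <- length(x) * 2L * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + dataSize, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # PCM
  writeBin(2L, con, size = 2, endian = "little") # stereo
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 4L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, size = 4, endian = "little")
  writeBin(as.integer(rep(x, each = 2)), con, size = 2, endian = "little")
  close(con)

  rec <- readWav(path)
  expect_equal(samples(rec), x / 32768, tolerance = 1e-12)
})

test_that("unreadable and empty audio raise classed errors", {
  expect_error(readWav(file.path(tempdir(), "nope.wav")),
    class = "dyadiar_io_error")
})

test_that("frame grid drops the trailing partial window", {
  expect_equal(nFrames(frameGrid(sineRecording(50, 2.05), 0.1)), 20L)
  expect_equal(nFrames(frameGrid(sineRecording(50, 1.0), 0.1)), 10L)
  expect_equal(nFrames(frameGrid(sineRecording(50, 600, fs = 8000L), 0.1)), 6000L)
  expect_error(frameGrid(sineRecording(50, 0.05), 0.1),
    class = "dyadiar_validation_error")
})

test_that("annotation projection labels only fully covered frames", {
  grid <- makeGrid(1.0)
  s1 <- annotationToStream(annotation(0.0, 0.5, "P1"), grid)
  expect_equal(streamLabels(s1), c(rep("P1", 5), rep("NS", 5)))

  s2 <- annotationToStream(annotation(0.05, 0.25, "P2"), grid)
  expect_equal(streamLabels(s2)[1:3], c("NS", "P2", "NS"))

  empty <- annotationToStream(annotation(numeric(0), numeric(0), character(0)), grid)
  expect_true(all(streamLabels(empty) == "NS"))
})

test_that("annotation projection is order-invariant and round-trips", {
  grid <- makeGrid(3.0)
  ann <- annotation(c(0.0, 1.2, 2.1), c(0.8, 1.9, 2.8), c("P1", "P2", "P1"))
  # order invariance: constructor sorts, so scrambled input gives same stream
  scrambled <- annotation(c(2.1, 0.0, 1.2), c(2.8, 0.8, 1.9), c("P1", "P1", "P2"))
  expect_equal(
    streamLabels(annotationToStream(ann, grid)),
    streamLabels(annotationToStream(scrambled, grid))
  )
  # round trip for grid-aligned utterances: stream -> intervals -> stream
  st <- annotationToStream(ann, grid)
  st2 <- annotationToStream(streamToAnnotation(st), grid)
  expect_equal(streamLabels(st2), streamLabels(st))
})

test_that("overlapping utterances are rejected", {
  expect_error(annotation(c(0, 0.5), c(1.0, 1.5), c("P1", "P2")),
    class = "dyadiar_validation_error")
})

test_that("RTTM and CSV annotation formats round-trip", {
  ann <- annotation(c(0.5, 2.25, 4.0), c(1.75, 3.5, 5.5), c("P1", "P2", "P1"))
  rttm <- withr::local_tempfile(fileext = ".rttm")
  writeRttm(ann, rttm, fileId = "t1")
  back <- readRttm(rttm)
  expect_equal(utterances(back), utterances(ann), tolerance = 1e-3)

  csv <- withr::local_tempfile(fileext = ".csv")
  writeAnnotationCsv(ann, csv)
  expect_equal(utterances(readAnnotationCsv(csv)), utterances(ann))
})

test_that("frame label CSV round-trips a stream", {
  st <- labelStream(c("NS", "P1", "P1", "P2", "NS"), ALPHABET_DIARIZATION, 10)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLabelCsv(st, path)
  back <- readLabelCsv(path, ALPHABET_DIARIZATION)
  expect_equal(streamLabels(back), streamLabels(st))
  expect_equal(frameRate(back), 10)
})
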