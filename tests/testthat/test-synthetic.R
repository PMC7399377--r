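# Synthetic voice and dialogue generation: determinism, construction
# bounds, and agreement between audio, annotation and ground truth.

test_that("utterance synthesis: length, spectrum, determinism, linearity", {
  v <- voiceSpec(f0Hz = 110, jitterPct = 0)
  x <- synthVoiceUtterance(v, 1, 16000L, seed = 3)
  expect_length(x, 16000L)

  # dominant spectral peak within one DFT bin of the fundamental
  spec <- Mod(fft(x))[1:8000]
  peakHz <- (which.max(spec) - 1) * 16000 / 16000
  expect_lte(abs(peakHz - 110), 1)

  expect_identical(x, synthVoiceUtterance(v, 1, 16000L, seed = 3))
  expect_false(identical(x, synthVoiceUtterance(v, 1, 16000L, seed = 4)))

  v2 <- voiceSpec(f0Hz = 110, jitterPct = 0, amplitude = 0.2)
  y <- synthVoiceUtterance(v2, 1, 16000L, seed = 3)
  expect_equal(sqrt(mean(y^2)) / sqrt(mean(x^2)), 2, tolerance = 1e-9)
})

test_that("dialogue construction bounds and determinism", {
  d <- buildDialogue(
    voiceSpec(110), voiceSpec(210),
    dialogueSpec(durationS = 60, seed = 37)
  )
  expect_equal(length(samples(d@recording)), 60 * 16000)
  expect_length(d@truth, 6000L) # 100 frames/s ground truth
  speech <- sum(d@annotation@stopS - d@annotation@startS) / 60
  expect_gt(speech, 0.4)
  expect_lt(speech, 0.9)
  expect_setequal(unique(d@annotation@speaker), c("P1", "P2"))

  d2 <- buildDialogue(
    voiceSpec(110), voiceSpec(210),
    dialogueSpec(durationS = 60, seed = 37)
  )
  expect_identical(samples(d2@recording), samples(d@recording))
  expect_identical(streamLabels(d2@truth), streamLabels(d@truth))
})

test_that("pHold = 0 gives strict speaker alternation", {
  d <- buildDialogue(
    voiceSpec(110), voiceSpec(210),
    dialogueSpec(durationS = 60, pHold = 0, seed = 5)
  )
  spk <- d@annotation@speaker
  expect_true(all(spk[-1] != spk[-length(spk)]))
})

test_that("too-short dialogues fail validation", {
  expect_error(
    buildDialogue(voiceSpec(110), voiceSpec(210),
      dialogueSpec(durationS = 2, seed = 1)),
    class = "dyadiar_validation_error"
  )
})

test_that("100 fps truth agrees with the 0.1 s annotation stream outside transitions", {
  d <- buildDialogue(
    voiceSpec(110), voiceSpec(210),
    dialogueSpec(durationS = 45, seed = 41)
  )
  s <- summarizeReference(d@truth, 10)
  grid <- makeGrid(45)
  direct <- annotationToStream(d@annotation, grid)
  ok <- !s$excluded
  expect_identical(streamLabels(s$stream)[ok], streamLabels(direct)[ok])
})

test_that("identical voices leave the classifier at chance on speech frames", {
  confusion <- vapply(1:3, function(k) {
    d <- buildDialogue(
      voiceSpec(110), voiceSpec(110),
      dialogueSpec(durationS = 250, seed = 500 + k)
    )
    cfg <- pipelineConfig(learnSpan = c(0, 120), testSpan = c(120, 240),
      seed = k)
    res <- suppressMessages(
      runDyad(d@recording, d@annotation, cfg, truth = d@truth)
    )
    s <- summarizeReference(d@truth, 10)
    n <- min(length(s$stream), length(res$speaker))
    starts <- (seq_len(n) - 1) * 0.1
    sel <- !s$excluded[1:n] &
      streamLabels(s$stream)[1:n] %in% c("P1", "P2") &
      starts >= 120 & starts + 0.1 <= 240
    mean(streamLabels(res$speaker)[1:n][sel] !=
      streamLabels(s$stream)[1:n][sel])
  }, numeric(1))
  expect_gte(mean(confusion), 0.4)
  expect_lte(mean(confusion), 0.6)
})

test_that("corpus manifests record pairings and allow regeneration", {
  co <- buildCorpus(1, baseSpec = dialogueSpec(durationS = 30), seed = 2)
  expect_equal(nrow(co$manifest), 1L)

  co2 <- buildCorpus(3,
    separationGrid = list(c(110, 210), c(110, 120)),
    baseSpec = dialogueSpec(durationS = 30), seed = 2
  )
  expect_equal(co2$manifest$gap, c(100, 10, 100))
  regen <- corpusDialogue(co2$manifest[2, ], dialogueSpec(durationS = 30))
  expect_identical(
    samples(regen@recording), samples(co2$dialogues[[2]]@recording)
  )

  lazy <- buildCorpus(3,
    separationGrid = list(c(110, 210), c(110, 120)),
    baseSpec = dialogueSpec(durationS = 30), seed = 2, materialize = FALSE
  )
  expect_identical(lazy$manifest, co2$manifest)
  expect_true(all(vapply(lazy$dialogues, is.null, logical(1))))
})
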