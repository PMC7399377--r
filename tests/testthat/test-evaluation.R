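# Reference summarization with transitional-window exclusion, the DER
# decomposition, and corpus-level summaries.

diarStream <- function(labels, rate = 10) {
  labelStream(labels, ALPHABET_DIARIZATION, rate)
}

test_that("summarization keeps unanimous blocks and excludes transitional ones", {
  ref <- diarStream(c(rep("P1", 10), rep("P1", 6), rep("NS", 4)), rate = 100)
  s <- summarizeReference(ref, 10)
  expect_equal(streamLabels(s$stream)[1], "P1")
  expect_false(s$excluded[1])
  expect_true(s$excluded[2]) # 6 x P1 + 4 x NS is transitional

  allNs <- diarStream(rep("NS", 100), rate = 100)
  s2 <- summarizeReference(allNs, 10)
  expect_equal(streamLabels(s2$stream), rep("NS", 10))
  expect_false(any(s2$excluded))
  expect_equal(frameRate(s2$stream), 10)

  expect_error(summarizeReference(ref, 0), class = "dyadiar_validation_error")
})

test_that("a block is excluded iff its labels are non-unanimous (enumeration)", {
  labs <- ALPHABET_DIARIZATION
  pats <- expand.grid(a = labs, b = labs, c = labs, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pats))) {
    block <- unlist(pats[i, ], use.names = FALSE)
    s <- summarizeReference(diarStream(block, rate = 30), 3)
    expect_identical(s$excluded, length(unique(block)) > 1L)
    if (!s$excluded) expect_identical(streamLabels(s$stream), block[1])
  }
  # property at factor 10 over seeded random streams
  set.seed(23)
  for (rep in 1:20) {
    labels <- sample(labs, 200, replace = TRUE, prob = c(0.5, 0.25, 0.25))
    s <- summarizeReference(diarStream(labels, rate = 100), 10)
    blocks <- matrix(labels, nrow = 10)
    expect_identical(
      s$excluded,
      apply(blocks, 2, function(b) length(unique(b)) > 1L)
    )
  }
})

test_that("DER decomposition on hand-checked cases", {
  ref <- diarStream(c("P1", "P1", "P2", "P2", "NS"))
  same <- computeDer(ref, ref)
  expect_equal(unname(derComponents(same)), c(0, 0, 0, 0))

  hyp <- diarStream(c("P1", "P2", "P2", "NS", "P1"))
  r <- derComponents(computeDer(ref, hyp))
  expect_equal(unname(r["SpE"]), 20)
  expect_equal(unname(r["MSp"]), 20)
  expect_equal(unname(r["FASp"]), 20)
  expect_equal(unname(r["DER"]), 60)

  # global speaker swap on an all-speech reference: pure speaker error
  refSp <- diarStream(rep(c("P1", "P2"), 10))
  swap <- diarStream(rep(c("P2", "P1"), 10))
  expect_equal(unname(derComponents(computeDer(refSp, swap))["SpE"]), 100)
})

test_that("compute_der equals the per-frame counting oracle on random streams", {
  set.seed(29)
  for (rep in 1:50) {
    n <- sample(10:400, 1)
    ref <- sample(ALPHABET_DIARIZATION, n, replace = TRUE)
    hyp <- sample(ALPHABET_DIARIZATION, n, replace = TRUE)
    excl <- runif(n) < 0.1
    rep1 <- computeDer(diarStream(ref), diarStream(hyp), excl)

    # oracle: literal frame-by-frame counting
    spe <- msp <- fasp <- correct <- 0
    for (i in seq_len(n)) {
      if (excl[i]) next
      rs <- ref[i] != "NS"
      hs <- hyp[i] != "NS"
      if (rs && hs && ref[i] != hyp[i]) spe <- spe + 1
      else if (rs && !hs) msp <- msp + 1
      else if (!rs && hs) fasp <- fasp + 1
      else correct <- correct + 1
    }
    nScored <- sum(!excl)
    expect_equal(rep1@speakerErrorPct, 100 * spe / nScored)
    expect_equal(rep1@missedSpeechPct, 100 * msp / nScored)
    expect_equal(rep1@falseAlarmPct, 100 * fasp / nScored)
    # conservation: errors + correct account for every scored frame
    expect_equal(rep1@derPct + 100 * correct / nScored, 100)
    expect_equal(rep1@nScored + rep1@nExcluded, n)
  }
})

test_that("corpus summaries: stds, perfect correlation, group contrast", {
  mkReport <- function(spe, msp, fasp, id) {
    new("DERReport",
      speakerErrorPct = spe, missedSpeechPct = msp, falseAlarmPct = fasp,
      derPct = spe + msp + fasp, nScored = 100L, nExcluded = 0L, dyadId = id
    )
  }
  same <- lapply(1:4, function(i) mkReport(2, 1, 0.5, paste0("d", i)))
  s <- summarizeCorpus(same, oob = c(1, 2, 3, 4) / 100)
  expect_equal(s@groupStats$der_sd, 0)
  expect_equal(s@groupStats$der_mean, 3.5)

  spe <- c(1, 3, 5, 7, 2, 8)
  reports <- lapply(seq_along(spe), function(i) mkReport(spe[i], 1, 0, paste0("d", i)))
  s2 <- summarizeCorpus(reports, oob = spe / 100)
  expect_equal(s2@oobSpeCor$r, 1, tolerance = 1e-12)
  expect_equal(s2@oobSpeCor$df, length(spe) - 2)

  s3 <- summarizeCorpus(reports, oob = spe / 100,
    groups = c("easy", "easy", "easy", "hard", "hard", "hard"))
  expect_equal(nrow(s3@groupStats), 2)
  expect_true(is.finite(s3@groupTest$t))
})
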