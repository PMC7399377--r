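# Learning-set construction and the per-dyad random forest.

test_that("learning set contains exactly the fully covered speech frames", {
  grid <- makeGrid(20)
  feats <- fakeFeatures(nFrames(grid))
  ann <- annotation(c(0, 6), c(6, 12), c("P1", "P2"))
  ls <- buildLearningSet(feats, ann, grid, learnSpan = c(0, 20))
  expect_equal(nrow(ls@features), 120L)
  expect_equal(sum(ls@labels == "P1"), 60L)
  expect_equal(sum(ls@labels == "P2"), 60L)
  expect_equal(ls@speechMinutes[["P1"]], 0.1)

  # restricting the span restricts the rows
  ls2 <- buildLearningSet(feats, ann, grid, learnSpan = c(0, 11))
  expect_equal(sum(ls2@labels == "P2"), 50L)
})

test_that("learning-set preconditions are enforced", {
  grid <- makeGrid(20)
  feats <- fakeFeatures(nFrames(grid))
  oneSpeaker <- annotation(c(0, 8), c(7, 19), c("P1", "P1"))
  expect_error(
    buildLearningSet(feats, oneSpeaker, grid, c(0, 20)),
    class = "dyadiar_validation_error"
  )
  ann <- annotation(c(0, 6), c(6, 12), c("P1", "P2"))
  expect_error(
    buildLearningSet(feats, ann, grid, c(0, 30)),
    class = "dyadiar_validation_error"
  )
  # too few frames
  short <- annotation(c(0, 3), c(3, 6), c("P1", "P2"))
  expect_error(
    buildLearningSet(fakeFeatures(nFrames(makeGrid(8))), short,
      makeGrid(8), c(0, 8)),
    class = "dyadiar_validation_error"
  )
})

separableSet <- function(m = 300, seed = 1) {
  set.seed(seed)
  x <- cbind(rep(c(0, 1), each = m / 2), matrix(rnorm(m * 35), m, 35))
  colnames(x) <- FEATURE_NAMES
  learningSet(x, rep(c("P1", "P2"), each = m / 2))
}

test_that("OOB error: near 0 when separable, near 0.5 under permuted labels", {
  ls <- separableSet()
  mod <- trainDyadModel(ls, nTrees = 500, seed = 2)
  expect_lt(oobError(mod), 0.01)

  set.seed(3)
  lsPerm <- learningSet(ls@features, sample(ls@labels))
  modPerm <- trainDyadModel(lsPerm, nTrees = 500, seed = 2)
  expect_gt(oobError(modPerm), 0.40)
  expect_lt(oobError(modPerm), 0.60)
})

test_that("training is deterministic given the seed", {
  ls <- separableSet(seed = 5)
  feats <- fakeFeatures(200, seed = 6)
  a <- trainDyadModel(ls, nTrees = 100, seed = 9)
  b <- trainDyadModel(ls, nTrees = 100, seed = 9)
  expect_identical(oobError(a), oobError(b))
  expect_identical(
    streamLabels(predictSpeakerStream(a, feats)),
    streamLabels(predictSpeakerStream(b, feats))
  )
})

test_that("prediction labels every frame with a speaker, memorizes separable data", {
  ls <- separableSet(seed = 7)
  mod <- trainDyadModel(ls, nTrees = 100, seed = 1)

  zero <- fakeFeatures(10, seed = 8)
  zero@values[] <- 0
  lab <- streamLabels(predictSpeakerStream(mod, zero))
  expect_true(all(lab %in% c("P1", "P2"))) # never NS, even on junk input

  # a learning frame of class P1 in the separable setting predicts P1
  tr <- fakeFeatures(1, seed = 9)
  tr@values[1, ] <- ls@features[1, ]
  expect_equal(streamLabels(predictSpeakerStream(mod, tr)), "P1")

  expect_error(
    predictSpeakerStream(mod, new("FeatureMatrix",
      values = matrix(0, 2, 3, dimnames = list(NULL, c("a", "b", "c"))),
      windowS = 0.1, sourceId = "bad"
    )),
    class = "dyadiar_validation_error"
  )
})

test_that("swapping learning labels swaps predictions (up to vote ties)", {
  set.seed(12)
  m <- 200
  x <- cbind(matrix(rnorm(m * 36), m, 36))
  colnames(x) <- FEATURE_NAMES
  x[, 1] <- x[, 1] + rep(c(0, 1.5), each = m / 2)
  lab <- rep(c("P1", "P2"), each = m / 2)
  feats <- fakeFeatures(300, seed = 13)
  feats@values[, 1] <- feats@values[, 1] + rep(c(0, 1.5), length.out = 300)

  mA <- trainDyadModel(learningSet(x, lab), nTrees = 101, seed = 4)
  mB <- trainDyadModel(
    learningSet(x, ifelse(lab == "P1", "P2", "P1")), nTrees = 101, seed = 4
  )
  pA <- streamLabels(predictSpeakerStream(mA, feats))
  pB <- streamLabels(predictSpeakerStream(mB, feats))
  expect_gte(mean(pB == ifelse(pA == "P1", "P2", "P1")), 0.99)
})

test_that("degenerate constant-feature learning sets refuse to train", {
  x <- matrix(1, 200, 36, dimnames = list(NULL, FEATURE_NAMES))
  ls <- learningSet(x, rep(c("P1", "P2"), 100))
  expect_error(trainDyadModel(ls), class = "dyadiar_validation_error")
})

test_that("model bundles round-trip through disk", {
  ls <- separableSet(seed = 20)
  mod <- trainDyadModel(ls, nTrees = 50, seed = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  saveDyadModel(mod, path)
  back <- loadDyadModel(path)
  expect_identical(oobError(back), oobError(mod))
  feats <- fakeFeatures(50, seed = 21)
  expect_identical(
    streamLabels(predictSpeakerStream(back, feats)),
    streamLabels(predictSpeakerStream(mod, feats))
  )
})
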