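# Per-dyad speaker classification: learning-set construction from the
# human annotation, random-forest training with out-of-bag error, and
# frame-level speaker prediction.

#' Build the learning set for one dyad
#'
#' Selects exactly the frames inside `learnSpan` that the annotation labels
#' `P1` or `P2` (via [annotationToStream()]; frames only partially covered
#' by an utterance are excluded). Silence never enters the learning set.
#'
#' @param features the dyad's [FeatureMatrix-class].
#' @param ann the human [Annotation-class].
#' @param grid the [FrameGrid-class] shared by both.
#' @param learnSpan `c(start_s, stop_s)` of the annotated learning
#'   segment (the paper-style protocol uses the first 10 minutes).
#' @param dyadId dyad identifier.
#' @return A [LearningSet-class].
#' @export
buildLearningSet <- function(features, ann, grid, learnSpan,
                             dyadId = sourceId(features)) {
  assertThat(is(features, "FeatureMatrix"), "features must be a FeatureMatrix")
  assertThat(length(learnSpan) == 2L && learnSpan[1] < learnSpan[2],
    "learnSpan must be c(start_s, stop_s) with start < stop")
  if (learnSpan[1] < 0 || learnSpan[2] > nFrames(grid) * windowS(grid) + 1e-9)
    stopValidation("learnSpan lies outside the recording")

  stream <- annotationToStream(ann, grid)
  starts <- frameStarts(grid)
  inSpan <- starts >= learnSpan[1] - 1e-9 &
    (starts + windowS(grid)) <= learnSpan[2] + 1e-9
  lab <- streamLabels(stream)
  keep <- inSpan & lab %in% ALPHABET_SPEAKER
  if (!any(lab[inSpan] == "P1") || !any(lab[inSpan] == "P2"))
    stopValidation("both speakers must occur inside the learning span")

  learningSet(
    featureValues(features)[keep, , drop = FALSE], lab[keep],
    dyadId = dyadId, windowS = windowS(grid)
  )
}

#' Train the per-dyad random forest
#'
#' Grows `nTrees` CART classification trees (Gini impurity, unlimited
#' depth, feature subset of size `floor(sqrt(p))` at each split) on
#' bootstrap bags of the learning set, following Breiman's algorithm. The
#' out-of-bag error is the fraction of learning frames misclassified by
#' the majority vote of the trees that did not sample them; it is computed
#' from the learning set alone and serves as the dyad's generalization
#' estimate.
#'
#' @param ls a [LearningSet-class].
#' @param nTrees ensemble size, default 500.
#' @param seed integer seed controlling all training randomness.
#' @param mtry features tried per split; default `floor(sqrt(ncol))`.
#' @param bagMode `"replace"` (n-of-n bootstrap, default; required for the
#'   usual OOB semantics) or `"subsample"` (0.632·n without replacement).
#' @return A [DyadModel-class].
#' @export
trainDyadModel <- function(ls, nTrees = 500L, seed = 1L,
                           mtry = NULL, bagMode = c("replace", "subsample")) {
  assertThat(is(ls, "LearningSet"), "ls must be a LearningSet")
  bagMode <- match.arg(bagMode)
  x <- ls@features
  if (all(apply(x, 2L, function(col) length(unique(col)) == 1L)))
    stopValidation("degenerate learning set: all features are constant")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))

  y <- as.integer(ls@labels == "P2") # P1 -> 0, P2 -> 1
  fit <- .rfTrain(
    x, y, as.integer(nTrees), as.integer(mtry), 1L,
    bagMode == "replace", 0.632, as.integer(seed)
  )
  votes <- fit$oobVotes
  seen <- rowSums(votes) > 0
  oobPred <- as.integer(votes[, 2] > votes[, 1]) # tie -> P1 (class 0)
  oobErr <- if (any(seen)) mean(oobPred[seen] != y[seen]) else NA_real_

  new("DyadModel",
    trees = fit$trees, oobError = oobErr,
    featureSchema = colnames(x), dyadId = ls@dyadId,
    seed = as.integer(seed), nTrees = as.integer(nTrees),
    bagMode = bagMode
  )
}

#' Predict the speaker stream for a feature matrix
#'
#' Every frame receives a `P1`/`P2` label by majority vote over the
#' ensemble, ties broken deterministically toward `P1` (the
#' lexicographically smaller label). Silence frames are classified too;
#' the silence/VAD veto is applied later by [aggregateStreams()].
#'
#' @param model a [DyadModel-class].
#' @param features a [FeatureMatrix-class] with the model's feature schema.
#' @return A [LabelStream-class] over `P1`/`P2` at `1/windowS` frames/s.
#' @export
predictSpeakerStream <- function(model, features) {
  assertThat(is(model, "DyadModel"), "model must be a DyadModel")
  vals <- featureValues(features)
  if (!identical(colnames(vals), model@featureSchema))
    stopValidation("feature schema does not match the trained model")
  votes <- .rfPredict(model@trees, vals)
  labelStream(
    ifelse(votes[, 2] > votes[, 1], "P2", "P1"),
    ALPHABET_SPEAKER, 1 / windowS(features)
  )
}

#' Persist / load a trained dyad model
#'
#' The on-disk bundle is a versioned RDS containing the trees, feature
#' schema, seed and OOB error.
#'
#' @param model a [DyadModel-class].
#' @param path file path for the bundle.
#' @return [loadDyadModel()] returns the [DyadModel-class].
#' @export
saveDyadModel <- function(model, path) {
  saveRDS(list(format = "dyadiar-model-v1", model = model), path)
  invisible(path)
}

#' @rdname saveDyadModel
#' @export
loadDyadModel <- function(path) {
  if (!file.exists(path)) stopIO(sprintf("model bundle not found: %s", path))
  bundle <- readRDS(path)
  if (!identical(bundle$format, "dyadiar-model-v1"))
    stopIO("not a dyadiar model bundle")
  bundle$model
}
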