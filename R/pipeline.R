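# Per-dyad pipeline: silence detection -> VAD -> feature extraction ->
# learning-set construction -> forest training -> prediction ->
# aggregation, with optional DER evaluation against a reference stream.

#' Pipeline configuration
#'
#' Defaults follow the naturalistic protocol: 0.1 s analysis windows, a
#' 500-tree forest, the first 10 minutes annotated for learning and
#' minutes 10-20 used as the test span.
#'
#' @param windowS analysis window in seconds.
#' @param nTrees forest size.
#' @param learnSpan,testSpan `c(start_s, stop_s)`; must not overlap.
#'   `testSpan = NULL` evaluates over the whole recording outside nothing
#'   (i.e. all frames).
#' @param seed integer seed for the forest.
#' @param feature a [featureConfig()].
#' @param silence a [silenceConfig()].
#' @param vad a [vadDetector()].
#' @param outDir when non-NULL, all intermediate streams, the model bundle
#'   and the report are persisted there.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(windowS = 0.1, nTrees = 500L,
                           learnSpan = c(0, 600), testSpan = c(600, 1200),
                           seed = 1L, feature = featureConfig(),
                           silence = silenceConfig(),
                           vad = defaultVadDetector(), outDir = NULL) {
  if (!is.null(testSpan) &&
    testSpan[1] < learnSpan[2] && learnSpan[1] < testSpan[2])
    stopValidation("learnSpan and testSpan must not overlap")
  structure(
    list(
      windowS = windowS, nTrees = as.integer(nTrees),
      learnSpan = learnSpan, testSpan = testSpan,
      seed = as.integer(seed), feature = feature, silence = silence,
      vad = vad, outDir = outDir
    ),
    class = "PipelineConfig"
  )
}

#' Run the full diarization pipeline for one dyad
#'
#' Executes silence detection, voice activity detection, feature
#' extraction, learning-set construction from the annotation inside
#' `learnSpan`, forest training (logging the OOB error), frame-level
#' speaker prediction over the whole recording, and stream aggregation.
#' When a reference `truth` stream is supplied, it is summarized to the
#' prediction rate (transitional windows excluded) and scored over
#' `testSpan`.
#'
#' @param rec an [AudioRecording-class].
#' @param ann the human [Annotation-class] covering `learnSpan`.
#' @param config a [pipelineConfig()].
#' @param truth optional reference [LabelStream-class] over `NS`/`P1`/`P2`
#'   (e.g. at 100 frames/s from [buildDialogue()]).
#' @param dyadId dyad identifier.
#' @return A list with `diarization` ([DiarizationStream-class]), `model`
#'   ([DyadModel-class]), `report` ([DERReport-class] or `NULL`), and the
#'   intermediate `silence`, `vad`, `speaker` streams and `features`.
#' @export
runDyad <- function(rec, ann, config = pipelineConfig(), truth = NULL,
                    dyadId = sourceId(rec)) {
  assertThat(inherits(config, "PipelineConfig"), "config must be a PipelineConfig")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        sprintf("[%s] %s", name, conditionMessage(e)),
        class = class(e)[class(e) != "simpleError"]
      ))
    })
  }

  grid <- stage("frame-grid", frameGrid(rec, config$windowS))
  feats <- stage("features", featurizeRecording(rec, grid, config$feature))
  sil <- stage("silence", detectSilence(rec, grid, config$silence))
  vad <- stage("vad", detectVoiceActivity(rec, grid, config$vad, features = feats))
  ls <- stage("learning-set",
    buildLearningSet(feats, ann, grid, config$learnSpan, dyadId = dyadId))
  model <- stage("training",
    trainDyadModel(ls, nTrees = config$nTrees, seed = config$seed))
  message(sprintf("dyad %s: OOB error %.4f", dyadId, oobError(model)))
  spk <- stage("prediction", predictSpeakerStream(model, feats))
  diar <- stage("aggregation", aggregateStreams(sil, vad, spk))

  report <- NULL
  if (!is.null(truth)) {
    report <- stage("evaluation", evaluateDyad(
      truth, diar, grid, testSpan = config$testSpan, dyadId = dyadId
    ))
  }

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    pfx <- file.path(config$outDir, dyadId)
    writeLabelCsv(sil@stream, paste0(pfx, "_silence.csv"))
    writeLabelCsv(vad@stream, paste0(pfx, "_vad.csv"))
    writeLabelCsv(spk, paste0(pfx, "_speaker.csv"))
    writeLabelCsv(diar@stream, paste0(pfx, "_diarization.csv"))
    writeRttm(diar, paste0(pfx, ".rttm"), fileId = dyadId)
    saveDyadModel(model, paste0(pfx, "_model.rds"))
    if (!is.null(report)) {
      jsonlite::write_json(
        as.list(derComponents(report)), paste0(pfx, "_der.json"),
        auto_unbox = TRUE, digits = NA
      )
    }
  }

  list(
    diarization = diar, model = model, report = report,
    silence = sil, vad = vad, speaker = spk, features = feats,
    learningSet = ls
  )
}

#' Score a diarization against a high-rate reference over a test span
#'
#' Summarizes the reference to the prediction frame rate (excluding
#' transitional windows), restricts both streams to the frames lying
#' entirely inside `testSpan`, and computes the DER decomposition.
#'
#' @param truth reference [LabelStream-class] over `NS`/`P1`/`P2` at a
#'   rate that is an integer multiple of the prediction rate.
#' @param diar the [DiarizationStream-class] (or plain hypothesis stream).
#' @param grid the prediction [FrameGrid-class].
#' @param testSpan `c(start_s, stop_s)`, or `NULL` for the whole
#'   recording.
#' @param collarS optional forgiveness collar in seconds: summarized
#'   frames within this distance of a reference label change are also
#'   excluded. Default 0 — the transitional-window exclusion is the
#'   primary boundary mechanism.
#' @param dyadId identifier for the report.
#' @return A [DERReport-class].
#' @export
evaluateDyad <- function(truth, diar, grid, testSpan = NULL, collarS = 0,
                         dyadId = "dyad") {
  hyp <- if (is(diar, "DiarizationStream")) diar@stream else diar
  fac <- truth@frameRate * grid@windowS
  assertThat(abs(fac - round(fac)) < 1e-6,
    "reference rate must be an integer multiple of the prediction rate")
  summ <- summarizeReference(truth, round(fac))
  if (collarS > 0) {
    lab <- summ$stream@labels
    change <- which(lab[-1] != lab[-length(lab)]) # boundary after frame i
    halo <- ceiling(collarS / grid@windowS)
    for (i in change) {
      lo <- max(1L, i - halo + 1L)
      hi <- min(length(lab), i + halo)
      summ$excluded[lo:hi] <- TRUE
    }
  }

  n <- min(length(summ$stream@labels), length(hyp@labels))
  starts <- (seq_len(n) - 1) * grid@windowS
  keep <- if (is.null(testSpan)) {
    rep(TRUE, n)
  } else {
    starts >= testSpan[1] - 1e-9 & (starts + grid@windowS) <= testSpan[2] + 1e-9
  }
  ref <- labelStream(summ$stream@labels[seq_len(n)][keep],
    ALPHABET_DIARIZATION, 1 / grid@windowS)
  hypK <- labelStream(hyp@labels[seq_len(n)][keep],
    ALPHABET_DIARIZATION, 1 / grid@windowS)
  computeDer(ref, hypK, excluded = summ$excluded[seq_len(n)][keep],
    dyadId = dyadId)
}
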