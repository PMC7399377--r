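# Central S4 data classes shared by all pipeline stages.

#' Canonical label alphabets
#'
#' Frame-level label streams use one of four alphabets: silence detection
#' emits `SIL`/`NONSIL`, voice activity detection emits `VOICED`/`UNVOICED`,
#' the per-dyad speaker classifier emits `P1`/`P2`, and the aggregated
#' diarization (and any reference truth) uses `NS`/`P1`/`P2` where `NS`
#' is non-speech (silence or noise).
#'
#' @format Character vectors.
#' @name label-alphabets
#' @export
ALPHABET_SILENCE <- c("SIL", "NONSIL")

#' @rdname label-alphabets
#' @export
ALPHABET_VAD <- c("VOICED", "UNVOICED")

#' @rdname label-alphabets
#' @export
ALPHABET_SPEAKER <- c("P1", "P2")

#' @rdname label-alphabets
#' @export
ALPHABET_DIARIZATION <- c("NS", "P1", "P2")

#' Names of the 36 short-term features, in canonical column order
#'
#' Eight spectral/temporal descriptors, 13 MFCCs, 12 chroma bins, harmonic
#' ratio, fundamental frequency, and the HF500 high/low band energy ratio.
#'
#' @export
FEATURE_NAMES <- c(
  "energy", "zero_crossing_rate", "entropy_of_energy",
  "spectral_centroid", "spectral_spread", "spectral_entropy",
  "spectral_flux", "spectral_rolloff",
  paste0("mfcc_", 1:13),
  paste0("chroma_", 1:12),
  "harmonic_ratio", "f0", "hf500"
)

# ---------------------------------------------------------------- audio ----

#' AudioRecording: a mono audio signal
#'
#' Holds a single-channel amplitude sequence in `[-1, 1]` together with its
#' sample rate. All downstream analysis operates on this class; multi-channel
#' input is averaged to mono at read time.
#'
#' @slot samples numeric vector of amplitudes in `[-1, 1]`.
#' @slot sampleRate integer, Hz (at least 8000).
#' @slot sourceId identifier string used in output artifacts.
#'
#' @export
setClass("AudioRecording",
  slots = c(samples = "numeric", sampleRate = "integer", sourceId = "character")
)

setValidity("AudioRecording", function(object) {
  msg <- character()
  if (length(object@samples) == 0L) msg <- c(msg, "recording has no samples")
  if (anyNA(object@samples) || !all(is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (length(object@sampleRate) != 1L || object@sampleRate < 8000L)
    msg <- c(msg, "sampleRate must be a single integer >= 8000")
  if (length(object@samples) && max(abs(object@samples)) > 1 + 1e-6)
    msg <- c(msg, "samples must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct an AudioRecording
#'
#' @param samples numeric amplitude vector in `[-1, 1]` (mono).
#' @param sampleRate sample rate in Hz, at least 8000.
#' @param sourceId identifier string.
#' @return An [AudioRecording-class] object.
#' @export
audioRecording <- function(samples, sampleRate, sourceId = "recording") {
  newValidated("AudioRecording",
    samples = as.numeric(samples),
    sampleRate = as.integer(sampleRate),
    sourceId = as.character(sourceId)[1]
  )
}

#' @rdname dyadiar-accessors
#' @export
setMethod("samples", "AudioRecording", function(x) x@samples)

#' @rdname dyadiar-accessors
#' @export
setMethod("sampleRate", "AudioRecording", function(x) x@sampleRate)

#' @rdname dyadiar-accessors
#' @export
setMethod("sourceId", "AudioRecording", function(x) x@sourceId)

#' @rdname dyadiar-accessors
#' @export
setMethod("duration", "AudioRecording",
  function(x) length(x@samples) / x@sampleRate)

setMethod("show", "AudioRecording", function(object) {
  cat(sprintf(
    "AudioRecording '%s': %.2f s at %d Hz (%d samples)\n",
    object@sourceId, duration(object), object@sampleRate,
    length(object@samples)
  ))
})

# ----------------------------------------------------------- frame grid ----

#' FrameGrid: non-overlapping analysis windows
#'
#' Frame `k` (0-based) covers the half-open interval
#' `[k * windowS, (k + 1) * windowS)` seconds; a trailing partial window is
#' dropped. The default window of 0.1 s gives the 10 frames/s resolution at
#' which all features, label streams and predictions live.
#'
#' @slot windowS window width in seconds.
#' @slot nFrames number of complete frames.
#' @slot sampleRate sample rate of the underlying recording, Hz.
#'
#' @seealso [frameGrid()]
#' @export
setClass("FrameGrid",
  slots = c(windowS = "numeric", nFrames = "integer", sampleRate = "integer")
)

setValidity("FrameGrid", function(object) {
  if (object@windowS <= 0) return("windowS must be positive")
  if (object@nFrames < 1L) return("grid must contain at least one frame")
  TRUE
})

#' @rdname dyadiar-accessors
#' @export
setMethod("windowS", "FrameGrid", function(x) x@windowS)

#' @rdname dyadiar-accessors
#' @export
setMethod("nFrames", "FrameGrid", function(x) x@nFrames)

#' @rdname dyadiar-accessors
#' @export
setMethod("sampleRate", "FrameGrid", function(x) x@sampleRate)

setMethod("show", "FrameGrid", function(object) {
  cat(sprintf(
    "FrameGrid: %d frames of %.3f s (%.1f frames/s)\n",
    object@nFrames, object@windowS, 1 / object@windowS
  ))
})

# ----------------------------------------------------------- annotation ----

#' Annotation: human-labelled speaker utterances
#'
#' The learning-set annotation a human coder produces: utterance start/stop
#' times in seconds with a speaker identity (`P1` or `P2`). Utterances must
#' be non-overlapping (dyadic non-overlap assumption) and are kept sorted by
#' start time.
#'
#' @slot startS,stopS numeric vectors, seconds.
#' @slot speaker character vector over `P1`/`P2`.
#'
#' @seealso [annotation()], [annotationToStream()], [readRttm()]
#' @export
setClass("Annotation",
  slots = c(startS = "numeric", stopS = "numeric", speaker = "character")
)

setValidity("Annotation", function(object) {
  n <- length(object@startS)
  if (length(object@stopS) != n || length(object@speaker) != n)
    return("startS, stopS and speaker must have equal length")
  if (n == 0L) return(TRUE)
  if (!all(object@speaker %in% ALPHABET_SPEAKER))
    return("speaker labels must be 'P1' or 'P2'")
  if (any(object@startS >= object@stopS))
    return("every utterance needs startS < stopS")
  if (is.unsorted(object@startS))
    return("utterances must be sorted by start time")
  if (n > 1L && any(object@stopS[-n] > object@startS[-1] + 1e-9))
    return("utterances overlap; dyadic annotations must be non-overlapping")
  TRUE
})

#' Construct an Annotation
#'
#' @param startS,stopS utterance start/stop times in seconds.
#' @param speaker speaker labels, `"P1"` or `"P2"`.
#' @return An [Annotation-class] object (sorted by start time).
#' @export
annotation <- function(startS, stopS, speaker) {
  o <- order(startS)
  newValidated("Annotation",
    startS = as.numeric(startS)[o], stopS = as.numeric(stopS)[o],
    speaker = as.character(speaker)[o]
  )
}

#' @rdname dyadiar-accessors
#' @export
setMethod("utterances", "Annotation", function(x) {
  data.frame(start_s = x@startS, stop_s = x@stopS, speaker = x@speaker)
})

setMethod("show", "Annotation", function(object) {
  n <- length(object@startS)
  cat(sprintf(
    "Annotation: %d utterances (%d P1, %d P2), %.1f s total speech\n",
    n, sum(object@speaker == "P1"), sum(object@speaker == "P2"),
    sum(object@stopS - object@startS)
  ))
})

#' Length of an Annotation (number of utterances)
#' @param x an [Annotation-class].
#' @export
setMethod("length", "Annotation", function(x) length(x@startS))

# ---------------------------------------------------------- label stream ----

#' LabelStream: a per-frame categorical stream
#'
#' A categorical label per frame at a stated frame rate, over one of the
#' canonical alphabets (see [label-alphabets]).
#'
#' @slot labels character vector, one label per frame.
#' @slot alphabet allowed labels.
#' @slot frameRate frames per second.
#'
#' @export
setClass("LabelStream",
  slots = c(labels = "character", alphabet = "character", frameRate = "numeric")
)

setValidity("LabelStream", function(object) {
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    return("frameRate must be a positive scalar")
  if (!all(object@labels %in% object@alphabet))
    return("all labels must belong to the alphabet")
  TRUE
})

#' Construct a LabelStream
#'
#' @param labels character vector of per-frame labels.
#' @param alphabet allowed label set.
#' @param frameRate frames per second.
#' @return A [LabelStream-class] object.
#' @export
labelStream <- function(labels, alphabet, frameRate) {
  newValidated("LabelStream",
    labels = as.character(labels), alphabet = alphabet,
    frameRate = as.numeric(frameRate)
  )
}

#' @rdname dyadiar-accessors
#' @export
setMethod("streamLabels", "LabelStream", function(x) x@labels)

#' @rdname dyadiar-accessors
#' @export
setMethod("labelAlphabet", "LabelStream", function(x) x@alphabet)

#' @rdname dyadiar-accessors
#' @export
setMethod("frameRate", "LabelStream", function(x) x@frameRate)

#' Length of a LabelStream (number of frames)
#' @param x a [LabelStream-class].
#' @export
setMethod("length", "LabelStream", function(x) length(x@labels))

setMethod("show", "LabelStream", function(object) {
  tab <- table(factor(object@labels, levels = object@alphabet))
  cat(sprintf(
    "LabelStream: %d frames at %g frames/s [%s]\n",
    length(object@labels), object@frameRate,
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")
  ))
})

# -------------------------------------------------------- feature matrix ----

#' FeatureMatrix: short-term features per frame
#'
#' One row per frame of a [FrameGrid-class], one column per feature in
#' [FEATURE_NAMES] order (36 features by default). Values are always finite;
#' silent frames map to defined values (0 for most features, the log-floor
#' cepstrum for MFCCs).
#'
#' @slot values numeric matrix, frames x features, with column names.
#' @slot windowS analysis window in seconds.
#' @slot sourceId identifier of the originating recording.
#'
#' @seealso [featurizeRecording()]
#' @export
setClass("FeatureMatrix",
  slots = c(values = "matrix", windowS = "numeric", sourceId = "character")
)

setValidity("FeatureMatrix", function(object) {
  if (is.null(colnames(object@values)))
    return("feature matrix must have column names")
  if (anyNA(object@values) || !all(is.finite(object@values)))
    return("feature values must be finite (no NaN/Inf)")
  TRUE
})

#' @rdname dyadiar-accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname dyadiar-accessors
#' @export
setMethod("featureNames", "FeatureMatrix", function(x) colnames(x@values))

#' @rdname dyadiar-accessors
#' @export
setMethod("windowS", "FeatureMatrix", function(x) x@windowS)

#' @rdname dyadiar-accessors
#' @export
setMethod("sourceId", "FeatureMatrix", function(x) x@sourceId)

#' @rdname dyadiar-accessors
#' @export
setMethod("nFrames", "FeatureMatrix", function(x) nrow(x@values))

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf(
    "FeatureMatrix '%s': %d frames x %d features (window %.3f s)\n",
    object@sourceId, nrow(object@values), ncol(object@values), object@windowS
  ))
})

# ------------------------------------------------------ detection results ----

#' SilenceResult: adaptive silence detection output
#'
#' @slot stream `SIL`/`NONSIL` [LabelStream-class].
#' @slot threshold the per-recording intensity threshold (mean-square
#'   frame energy units).
#' @slot degenerate TRUE when the recording had no low-intensity mode and
#'   everything was labelled `NONSIL`.
#'
#' @seealso [detectSilence()]
#' @export
setClass("SilenceResult",
  slots = c(stream = "LabelStream", threshold = "numeric", degenerate = "logical")
)

#' @rdname dyadiar-accessors
#' @export
setMethod("silenceThreshold", "SilenceResult", function(x) x@threshold)

#' @rdname dyadiar-accessors
#' @export
setMethod("streamLabels", "SilenceResult", function(x) x@stream@labels)

setMethod("show", "SilenceResult", function(object) {
  cat(sprintf(
    "SilenceResult: threshold %.3g, %d/%d frames SIL%s\n",
    object@threshold, sum(object@stream@labels == "SIL"),
    length(object@stream@labels),
    if (object@degenerate) " (degenerate: no silence mode)" else ""
  ))
})

#' VadResult: voice activity detection output
#'
#' @slot stream `VOICED`/`UNVOICED` [LabelStream-class].
#' @slot detectorId identifier of the detector that produced it.
#'
#' @seealso [detectVoiceActivity()]
#' @export
setClass("VadResult",
  slots = c(stream = "LabelStream", detectorId = "character")
)

#' @rdname dyadiar-accessors
#' @export
setMethod("streamLabels", "VadResult", function(x) x@stream@labels)

setMethod("show", "VadResult", function(object) {
  cat(sprintf(
    "VadResult (%s): %d/%d frames VOICED\n", object@detectorId,
    sum(object@stream@labels == "VOICED"), length(object@stream@labels)
  ))
})

# ------------------------------------------------------------ classifier ----

#' LearningSet: annotated speech frames for one dyad
#'
#' Only spoken frames (labelled `P1` or `P2`, no silence) enter the learning
#' set; both speakers must be present and at least 100 frames are required.
#'
#' @slot features numeric matrix, frames x features.
#' @slot labels character vector over `P1`/`P2`.
#' @slot dyadId dyad identifier.
#' @slot speechMinutes named numeric: minutes of speech per speaker.
#'
#' @seealso [buildLearningSet()]
#' @export
setClass("LearningSet",
  slots = c(
    features = "matrix", labels = "character",
    dyadId = "character", speechMinutes = "numeric"
  )
)

setValidity("LearningSet", function(object) {
  m <- nrow(object@features)
  if (length(object@labels) != m)
    return("labels length must match feature rows")
  if (!all(object@labels %in% ALPHABET_SPEAKER))
    return("learning labels must be 'P1'/'P2' (no silence)")
  if (m < 100L)
    return("learning set too small (fewer than 100 speech frames)")
  if (length(unique(object@labels)) < 2L)
    return("both speakers must be present in the learning set")
  if (is.null(colnames(object@features)))
    return("learning features must carry column names")
  TRUE
})

#' Construct a LearningSet directly from a feature matrix and labels
#'
#' Mostly useful for simulation studies; the pipeline builds learning sets
#' from annotations via [buildLearningSet()].
#'
#' @param features numeric matrix with column names (frames x features).
#' @param labels `"P1"`/`"P2"` per row.
#' @param dyadId dyad identifier.
#' @param windowS frame width in seconds used to derive speech minutes.
#' @return A [LearningSet-class].
#' @export
learningSet <- function(features, labels, dyadId = "dyad", windowS = 0.1) {
  mins <- c(
    P1 = sum(labels == "P1") * windowS / 60,
    P2 = sum(labels == "P2") * windowS / 60
  )
  newValidated("LearningSet",
    features = features, labels = as.character(labels),
    dyadId = dyadId, speechMinutes = mins
  )
}

#' @rdname dyadiar-accessors
#' @export
setMethod("dyadId", "LearningSet", function(x) x@dyadId)

setMethod("show", "LearningSet", function(object) {
  cat(sprintf(
    "LearningSet '%s': %d frames (%d P1, %d P2); %.2f / %.2f min speech\n",
    object@dyadId, nrow(object@features),
    sum(object@labels == "P1"), sum(object@labels == "P2"),
    object@speechMinutes[["P1"]], object@speechMinutes[["P2"]]
  ))
})

#' DyadModel: a trained per-dyad random forest
#'
#' A bagged ensemble of CART trees trained on one dyad's learning set. The
#' out-of-bag (OOB) error — the error of each learning frame under the
#' trees that did not sample it — is stored as the model's built-in
#' generalization estimate.
#'
#' @slot trees list of flattened decision trees (internal layout).
#' @slot oobError OOB misclassification fraction in `[0, 1]`.
#' @slot featureSchema ordered feature names the model expects.
#' @slot dyadId dyad identifier.
#' @slot seed integer seed that controlled all training randomness.
#' @slot nTrees number of trees (default 500).
#' @slot bagMode `"replace"` (Breiman bootstrap) or `"subsample"`.
#'
#' @seealso [trainDyadModel()], [predictSpeakerStream()]
#' @export
setClass("DyadModel",
  slots = c(
    trees = "list", oobError = "numeric", featureSchema = "character",
    dyadId = "character", seed = "integer", nTrees = "integer",
    bagMode = "character"
  )
)

setValidity("DyadModel", function(object) {
  if (length(object@trees) != object@nTrees)
    return("tree count must equal nTrees")
  if (object@oobError < 0 || object@oobError > 1)
    return("oobError must lie in [0, 1]")
  TRUE
})

#' @rdname dyadiar-accessors
#' @export
setMethod("oobError", "DyadModel", function(x) x@oobError)

#' @rdname dyadiar-accessors
#' @export
setMethod("featureSchema", "DyadModel", function(x) x@featureSchema)

#' @rdname dyadiar-accessors
#' @export
setMethod("dyadId", "DyadModel", function(x) x@dyadId)

setMethod("show", "DyadModel", function(object) {
  cat(sprintf(
    "DyadModel '%s': %d trees, OOB error %.3f (seed %d, bagging: %s)\n",
    object@dyadId, object@nTrees, object@oobError, object@seed,
    object@bagMode
  ))
})

# ----------------------------------------------------------- diarization ----

#' DiarizationStream: the final aggregated per-frame diarization
#'
#' Labels over `NS`/`P1`/`P2` with per-frame provenance: `silence` when the
#' silence detector claimed the frame, `vad_noise` when VAD vetoed it, and
#' `classifier` when the speaker label came from the forest.
#'
#' @slot stream [LabelStream-class] over `NS`/`P1`/`P2`.
#' @slot provenance character per frame: `silence`, `vad_noise`, `classifier`.
#'
#' @seealso [aggregateStreams()]
#' @export
setClass("DiarizationStream",
  slots = c(stream = "LabelStream", provenance = "character")
)

setValidity("DiarizationStream", function(object) {
  if (length(object@provenance) != length(object@stream@labels))
    return("provenance must align with the stream")
  spk <- object@stream@labels %in% c("P1", "P2")
  if (any(spk & object@provenance != "classifier"))
    return("speaker frames must carry classifier provenance")
  if (any(!spk & !object@provenance %in% c("silence", "vad_noise")))
    return("NS frames must carry silence or vad_noise provenance")
  TRUE
})

#' @rdname dyadiar-accessors
#' @export
setMethod("streamLabels", "DiarizationStream", function(x) x@stream@labels)

#' @rdname dyadiar-accessors
#' @export
setMethod("provenance", "DiarizationStream", function(x) x@provenance)

#' Length of a DiarizationStream (number of frames)
#' @param x a [DiarizationStream-class].
#' @export
setMethod("length", "DiarizationStream", function(x) length(x@stream@labels))

setMethod("show", "DiarizationStream", function(object) {
  show(object@stream)
})

# ------------------------------------------------------------- reporting ----

#' DERReport: diarization error decomposition for one dyad
#'
#' Percentages over scored (non-excluded) summarized frames:
#' speaker error (SpE), missed speech (MSp), false alarm speech (FASp),
#' and their sum, the diarization error rate (DER).
#'
#' @slot speakerErrorPct,missedSpeechPct,falseAlarmPct,derPct percentages.
#' @slot nScored number of scored frames.
#' @slot nExcluded number of transitional frames excluded from scoring.
#' @slot dyadId dyad identifier.
#'
#' @seealso [computeDer()]
#' @export
setClass("DERReport",
  slots = c(
    speakerErrorPct = "numeric", missedSpeechPct = "numeric",
    falseAlarmPct = "numeric", derPct = "numeric",
    nScored = "integer", nExcluded = "integer", dyadId = "character"
  )
)

setValidity("DERReport", function(object) {
  comp <- c(
    object@speakerErrorPct, object@missedSpeechPct,
    object@falseAlarmPct
  )
  if (any(comp < 0)) return("error components must be non-negative")
  if (abs(object@derPct - sum(comp)) > 1e-9)
    return("derPct must equal SpE + MSp + FASp")
  TRUE
})

#' @rdname dyadiar-accessors
#' @export
setMethod("derComponents", "DERReport", function(x) {
  c(
    SpE = x@speakerErrorPct, MSp = x@missedSpeechPct,
    FASp = x@falseAlarmPct, DER = x@derPct
  )
})

#' @rdname dyadiar-accessors
#' @export
setMethod("dyadId", "DERReport", function(x) x@dyadId)

setMethod("show", "DERReport", function(object) {
  cat(sprintf(
    "DERReport '%s': DER %.2f%% (SpE %.2f, MSp %.2f, FASp %.2f); %d frames scored, %d transitional excluded\n",
    object@dyadId, object@derPct, object@speakerErrorPct,
    object@missedSpeechPct, object@falseAlarmPct,
    object@nScored, object@nExcluded
  ))
})

#' CorpusSummary: grouped error summaries over many dyads
#'
#' Per-group mean/std of each error component, the Pearson correlation
#' between dyadic OOB error and dyadic speaker error, and a Welch t test
#' of DER between the two groups (when exactly two are present).
#'
#' @slot groupStats data.frame of per-group means and stds.
#' @slot oobSpeCor list with `r`, `df`, `p`.
#' @slot groupTest list with `t`, `df`, `p` (or empty when not applicable).
#' @slot nDyads number of dyads summarized.
#'
#' @seealso [summarizeCorpus()]
#' @export
setClass("CorpusSummary",
  slots = c(
    groupStats = "data.frame", oobSpeCor = "list",
    groupTest = "list", nDyads = "integer"
  )
)

setMethod("show", "CorpusSummary", function(object) {
  cat(sprintf("CorpusSummary over %d dyads\n", object@nDyads))
  print(object@groupStats, row.names = FALSE)
  if (length(object@oobSpeCor)) {
    cat(sprintf(
      "OOB ~ SpE correlation: r(%d) = %.3f, p = %.3g\n",
      object@oobSpeCor$df, object@oobSpeCor$r, object@oobSpeCor$p
    ))
  }
  if (length(object@groupTest)) {
    cat(sprintf(
      "Group DER contrast (Welch): t(%.1f) = %.2f, p = %.3g\n",
      object@groupTest$df, object@groupTest$t, object@groupTest$p
    ))
  }
})

# ------------------------------------------------------------- synthetic ----

#' SyntheticDialogue: a generated dyadic dialogue with ground truth
#'
#' @slot recording the synthesized [AudioRecording-class].
#' @slot truth reference [LabelStream-class] over `NS`/`P1`/`P2` at
#'   100 frames/s (the corpus-style frame rate).
#' @slot annotation the full [Annotation-class] of generated utterances.
#' @slot voiceSpecs list of the two voice specifications.
#' @slot dialogueSpec the dialogue specification used.
#'
#' @seealso [buildDialogue()]
#' @export
setClass("SyntheticDialogue",
  slots = c(
    recording = "AudioRecording", truth = "LabelStream",
    annotation = "Annotation", voiceSpecs = "list", dialogueSpec = "list"
  )
)

setMethod("show", "SyntheticDialogue", function(object) {
  cat("SyntheticDialogue\n  ")
  show(object@recording)
  cat("  ")
  show(object@annotation)
})
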