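# Voice activity detection. The pipeline treats the detector as a plug-in
# contract so that an external system (e.g. an MLP-based VAD) can be
# swapped in; the default detector is a fixed decision rule over
# harmonicity and spectral-flatness cues computed from the 36-feature
# matrix, calibrated only on this package's synthetic material.

#' Construct a voice activity detector (plug-in contract)
#'
#' A detector is a function mapping a per-frame feature matrix (columns as
#' in [FEATURE_NAMES]) plus a context half-width (frames) to a logical
#' vector, `TRUE` for voiced frames.
#'
#' @param fun `function(features, contextWidth)` returning a logical
#'   vector with one element per row of `features`.
#' @param id detector identifier carried into [VadResult-class].
#' @param contextWidth context half-width in frames passed to `fun`.
#' @return A `VadDetector` object.
#' @export
vadDetector <- function(fun, id, contextWidth = 0L) {
  assertThat(is.function(fun), "fun must be a function")
  structure(
    list(fun = fun, id = as.character(id), contextWidth = as.integer(contextWidth)),
    class = "VadDetector"
  )
}

#' Default voice activity detector
#'
#' Scores each frame as `0.6 * harmonic_ratio + 0.4 * (1 -
#' spectral_entropy)` and declares it voiced when the score exceeds
#' `threshold`. Voiced speech is strongly harmonic with a peaked spectrum
#' (score near 0.9); wide-band noise is inharmonic and spectrally flat
#' (score near 0.1); silent frames score at most 0.4. When
#' `contextWidth > 0` the score is mean-smoothed over `2*contextWidth + 1`
#' frames before thresholding.
#'
#' @param threshold decision threshold, default 0.5.
#' @param contextWidth smoothing half-width in frames, default 0 (off).
#' @return A [vadDetector()].
#' @export
defaultVadDetector <- function(threshold = 0.5, contextWidth = 0L) {
  vadDetector(
    function(features, ctx) {
      score <- 0.6 * features[, "harmonic_ratio"] +
        0.4 * (1 - features[, "spectral_entropy"])
      if (ctx > 0L && length(score) > 1L) {
        k <- 2L * ctx + 1L
        score <- as.numeric(stats::filter(score, rep(1 / k, k), sides = 2))
        score[is.na(score)] <- 0 # edge frames fall back to unvoiced bias
      }
      score > threshold
    },
    id = sprintf("harmonicity-flatness(thr=%.2f)", threshold),
    contextWidth = contextWidth
  )
}

#' Detect voice activity over the whole recording
#'
#' Runs the detector on every frame (not only non-silence frames);
#' precedence between silence, VAD and the speaker classifier is resolved
#' later by [aggregateStreams()].
#'
#' @param rec an [AudioRecording-class].
#' @param grid a [FrameGrid-class].
#' @param detector a [vadDetector()]; default [defaultVadDetector()].
#' @param features optional precomputed [FeatureMatrix-class] (computed on
#'   the fly otherwise).
#' @return A [VadResult-class].
#' @export
detectVoiceActivity <- function(rec, grid, detector = defaultVadDetector(),
                                features = NULL) {
  assertThat(inherits(detector, "VadDetector"),
    "detector must be a VadDetector")
  if (is.null(features)) features <- featurizeRecording(rec, grid)
  voiced <- tryCatch(
    detector$fun(featureValues(features), detector$contextWidth),
    error = function(e) {
      stopIO(sprintf("VAD detector '%s' failed: %s", detector$id, conditionMessage(e)))
    }
  )
  assertThat(length(voiced) == nFrames(grid),
    "detector returned a stream of the wrong length")
  new("VadResult",
    stream = labelStream(
      ifelse(voiced, "VOICED", "UNVOICED"), ALPHABET_VAD, 1 / grid@windowS
    ),
    detectorId = detector$id
  )
}
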