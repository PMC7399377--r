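# Frame grid construction and conversion between utterance annotations and
# frame-level label streams.

#' Build the analysis frame grid for a recording
#'
#' Divides the recording into non-overlapping windows of `windowS` seconds
#' (0.1 s by default); a trailing partial window is dropped. Frame `k`
#' (0-based) covers `[k * windowS, (k + 1) * windowS)`.
#'
#' @param rec an [AudioRecording-class].
#' @param windowS window width in seconds (> 0).
#' @return A [FrameGrid-class].
#' @export
frameGrid <- function(rec, windowS = 0.1) {
  assertThat(is(rec, "AudioRecording"), "rec must be an AudioRecording")
  assertThat(windowS > 0, "windowS must be positive")
  n <- floor(duration(rec) / windowS + 1e-9)
  if (n < 1) stopValidation("window is longer than the recording")
  new("FrameGrid",
    windowS = windowS, nFrames = as.integer(n),
    sampleRate = sampleRate(rec)
  )
}

#' Frame start times in seconds
#' @param grid a [FrameGrid-class].
#' @return Numeric vector of `nFrames` start times.
#' @export
frameStarts <- function(grid) {
  (seq_len(grid@nFrames) - 1) * grid@windowS
}

# sample index ranges (1-based start, count) for each frame
.frameSampleIndex <- function(grid) {
  spf <- floor(grid@windowS * grid@sampleRate + 1e-9)
  starts <- floor((seq_len(grid@nFrames) - 1) * grid@windowS * grid@sampleRate + 1e-9) + 1L
  list(start = as.integer(starts), samplesPerFrame = as.integer(spf))
}

#' Project an utterance annotation onto a frame grid
#'
#' A frame is labelled `P1`/`P2` iff it lies *entirely* inside one
#' utterance; frames only partially covered by speech are conservatively
#' labelled `NS` so the classifier is never taught on mixed frames. All
#' remaining frames are `NS`.
#'
#' @param ann an [Annotation-class].
#' @param grid a [FrameGrid-class].
#' @return A [LabelStream-class] over `NS`/`P1`/`P2` at `1/windowS` frames/s.
#' @export
annotationToStream <- function(ann, grid) {
  assertThat(is(ann, "Annotation"), "ann must be an Annotation")
  assertThat(is(grid, "FrameGrid"), "grid must be a FrameGrid")
  w <- grid@windowS
  labels <- rep("NS", grid@nFrames)
  eps <- 1e-9
  for (i in seq_along(ann@startS)) {
    # frames k (0-based) with k*w >= start and (k+1)*w <= stop
    kFirst <- ceiling(ann@startS[i] / w - eps)
    kLast <- floor(ann@stopS[i] / w + eps) - 1
    if (kLast >= kFirst) {
      lo <- max(kFirst, 0) + 1
      hi <- min(kLast, grid@nFrames - 1) + 1
      if (hi >= lo) labels[lo:hi] <- ann@speaker[i]
    }
  }
  labelStream(labels, ALPHABET_DIARIZATION, 1 / w)
}

#' Convert a frame-level stream back to utterance intervals
#'
#' Maximal runs of identical `P1`/`P2` labels become utterances; `NS`
#' frames separate them. Inverse of [annotationToStream()] for grid-aligned
#' annotations.
#'
#' @param stream a [LabelStream-class] over `NS`/`P1`/`P2`.
#' @return An [Annotation-class].
#' @export
streamToAnnotation <- function(stream) {
  assertThat(is(stream, "LabelStream"), "stream must be a LabelStream")
  w <- 1 / stream@frameRate
  lab <- stream@labels
  r <- rle(lab)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths
  keep <- r$values %in% c("P1", "P2")
  annotation(starts[keep] * w, stops[keep] * w, r$values[keep])
}
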