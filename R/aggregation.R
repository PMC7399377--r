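# Merge of the three per-frame information streams into the final
# diarization. Precedence: silence wins; then the VAD may veto a frame as
# noise; only frames that survive both receive the classifier's speaker
# label.

#' Aggregate silence, VAD and speaker streams
#'
#' Per frame: `SIL` stays non-speech regardless of the other streams;
#' non-silence frames judged `UNVOICED` by the VAD become non-speech
#' (noise); non-silence `VOICED` frames take the classifier's `P1`/`P2`
#' label. The output records per-frame provenance (`silence`, `vad_noise`
#' or `classifier`).
#'
#' @param sil [LabelStream-class] over `SIL`/`NONSIL` (or a
#'   [SilenceResult-class]).
#' @param vad [LabelStream-class] over `VOICED`/`UNVOICED` (or a
#'   [VadResult-class]).
#' @param spk [LabelStream-class] over `P1`/`P2`.
#' @return A [DiarizationStream-class] over `NS`/`P1`/`P2`.
#' @export
aggregateStreams <- function(sil, vad, spk) {
  if (is(sil, "SilenceResult")) sil <- sil@stream
  if (is(vad, "VadResult")) vad <- vad@stream
  assertThat(
    is(sil, "LabelStream") && is(vad, "LabelStream") && is(spk, "LabelStream"),
    "sil, vad and spk must be LabelStreams"
  )
  n <- length(sil@labels)
  if (length(vad@labels) != n || length(spk@labels) != n)
    stopValidation("the three streams must share one frame grid")
  assertThat(all(sil@labels %in% ALPHABET_SILENCE), "sil must be SIL/NONSIL")
  assertThat(all(vad@labels %in% ALPHABET_VAD), "vad must be VOICED/UNVOICED")
  assertThat(all(spk@labels %in% ALPHABET_SPEAKER), "spk must be P1/P2")

  out <- rep("NS", n)
  prov <- rep("silence", n)
  nonsil <- sil@labels == "NONSIL"
  noise <- nonsil & vad@labels == "UNVOICED"
  speech <- nonsil & vad@labels == "VOICED"
  prov[noise] <- "vad_noise"
  out[speech] <- spk@labels[speech]
  prov[speech] <- "classifier"

  new("DiarizationStream",
    stream = labelStream(out, ALPHABET_DIARIZATION, sil@frameRate),
    provenance = prov
  )
}
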