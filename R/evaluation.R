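# DER scoring against a reference stream, with corpus-style frame-rate
# summarization, transitional-window exclusion, and grouped summaries.

#' Summarize a high-rate reference stream to the prediction rate
#'
#' Blocks of `factor` consecutive reference labels (e.g. 10 frames at
#' 100 frames/s -> one 0.1 s prediction window) map to their label when
#' unanimous; transitional blocks containing more than one label class are
#' marked excluded and do not enter scoring. A trailing partial block is
#' dropped.
#'
#' @param ref a [LabelStream-class] (typically `NS`/`P1`/`P2` at 100
#'   frames/s).
#' @param factor summarization factor (reference rate / prediction rate).
#' @return A list with `stream` (a [LabelStream-class] at
#'   `frameRate(ref)/factor`; excluded blocks carry their majority label,
#'   first-seen on ties) and `excluded` (logical mask).
#' @export
summarizeReference <- function(ref, factor) {
  assertThat(is(ref, "LabelStream"), "ref must be a LabelStream")
  factor <- as.integer(factor)
  if (is.na(factor) || factor <= 0L) stopValidation("factor must be positive")
  assertThat(length(ref@labels) >= factor, "stream shorter than one block")

  nOut <- length(ref@labels) %/% factor
  blocks <- matrix(ref@labels[seq_len(nOut * factor)], nrow = factor)
  first <- blocks[1L, ]
  unanimous <- colSums(blocks != rep(first, each = factor)) == 0L
  # excluded blocks still need a defined label for bookkeeping: majority
  out <- first
  if (any(!unanimous)) {
    out[!unanimous] <- apply(blocks[, !unanimous, drop = FALSE], 2L,
      function(b) names(which.max(table(base::factor(b, levels = unique(b)))))
    )
  }
  list(
    stream = labelStream(out, ref@alphabet, ref@frameRate / factor),
    excluded = !unanimous
  )
}

#' Compute the diarization error decomposition
#'
#' Over the scored (non-excluded) frames: speaker error SpE is the
#' percentage of frames where both streams see speech but disagree on the
#' speaker; missed speech MSp where reference speech is predicted
#' non-speech; false alarm FASp where reference non-speech is predicted as
#' speech. DER = SpE + MSp + FASp. Speaker labels are matched under the
#' fixed identity mapping given by the supervision — no optimal
#' relabelling.
#'
#' @param ref reference [LabelStream-class] over `NS`/`P1`/`P2` (already
#'   summarized to the prediction rate).
#' @param hyp hypothesis [LabelStream-class] or [DiarizationStream-class].
#' @param excluded optional logical mask of transitional frames to skip.
#' @param dyadId identifier carried into the report.
#' @return A [DERReport-class].
#' @export
computeDer <- function(ref, hyp, excluded = NULL, dyadId = "dyad") {
  if (is(hyp, "DiarizationStream")) hyp <- hyp@stream
  assertThat(is(ref, "LabelStream") && is(hyp, "LabelStream"),
    "ref and hyp must be LabelStreams")
  n <- length(ref@labels)
  if (length(hyp@labels) != n)
    stopValidation("reference and hypothesis must have equal length")
  if (is.null(excluded)) excluded <- rep(FALSE, n)
  assertThat(length(excluded) == n, "excluded mask must match stream length")

  r <- ref@labels[!excluded]
  h <- hyp@labels[!excluded]
  nScored <- length(r)
  refSpeech <- r %in% ALPHABET_SPEAKER
  hypSpeech <- h %in% ALPHABET_SPEAKER
  spe <- 100 * sum(refSpeech & hypSpeech & r != h) / nScored
  msp <- 100 * sum(refSpeech & !hypSpeech) / nScored
  fasp <- 100 * sum(!refSpeech & hypSpeech) / nScored

  new("DERReport",
    speakerErrorPct = spe, missedSpeechPct = msp, falseAlarmPct = fasp,
    derPct = spe + msp + fasp,
    nScored = as.integer(nScored), nExcluded = as.integer(sum(excluded)),
    dyadId = dyadId
  )
}

#' Summarize DER reports over a corpus of dyads
#'
#' Produces per-group means and standard deviations of each error
#' component, the Pearson correlation between dyadic OOB error and dyadic
#' speaker error (the paper-style quality-control check), and — when
#' exactly two groups are present — a Welch two-sample t test of DER
#' between them.
#'
#' @param reports list of [DERReport-class] objects.
#' @param oob per-dyad OOB error fractions (same order as `reports`).
#' @param groups per-dyad group labels (e.g. same-sex vs different-sex
#'   analogue); a single group when `NULL`.
#' @return A [CorpusSummary-class].
#' @export
summarizeCorpus <- function(reports, oob = NULL, groups = NULL) {
  assertThat(length(reports) >= 3L, "need at least 3 dyads to summarize")
  comp <- t(vapply(reports, derComponents, numeric(4)))
  nd <- nrow(comp)
  if (is.null(groups)) groups <- rep("all", nd)
  assertThat(length(groups) == nd, "one group label per dyad required")

  stats <- do.call(rbind, lapply(split(seq_len(nd), groups), function(ix) {
    m <- comp[ix, , drop = FALSE]
    data.frame(
      group = groups[ix[1]], n = length(ix),
      der_mean = mean(m[, "DER"]), der_sd = if (length(ix) > 1) sd(m[, "DER"]) else NA_real_,
      spe_mean = mean(m[, "SpE"]), spe_sd = if (length(ix) > 1) sd(m[, "SpE"]) else NA_real_,
      msp_mean = mean(m[, "MSp"]), msp_sd = if (length(ix) > 1) sd(m[, "MSp"]) else NA_real_,
      fasp_mean = mean(m[, "FASp"]), fasp_sd = if (length(ix) > 1) sd(m[, "FASp"]) else NA_real_
    )
  }))
  rownames(stats) <- NULL

  corRes <- list()
  if (!is.null(oob)) {
    assertThat(length(oob) == nd, "one OOB error per dyad required")
    if (sd(oob) > 0 && sd(comp[, "SpE"]) > 0) {
      ct <- cor.test(oob, comp[, "SpE"], method = "pearson")
      corRes <- list(
        r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value
      )
    } else {
      corRes <- list(r = NA_real_, df = nd - 2L, p = NA_real_)
    }
  }

  testRes <- list()
  if (length(unique(groups)) == 2L && all(table(groups) >= 2L)) {
    tt <- t.test(comp[, "DER"] ~ groups)
    testRes <- list(
      t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value
    )
  }

  new("CorpusSummary",
    groupStats = stats, oobSpeCor = corRes, groupTest = testRes,
    nDyads = as.integer(nd)
  )
}
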