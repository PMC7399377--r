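# Per-recording adaptive silence detection: a two-class Otsu split on the
# log of per-frame intensity (mean-square energy). Gain-invariant by
# construction: scaling the recording shifts all log intensities equally.

#' Estimate the per-recording silence threshold
#'
#' Finds the intensity threshold that best separates the low-intensity
#' (silence) mode from the high-intensity (speech) mode of the per-frame
#' log10 intensity histogram by minimizing intra-class variance (Otsu's
#' criterion). The returned value is on the intensity scale and lies
#' strictly between the observed minimum and maximum when both classes are
#' present.
#'
#' Recordings without a silence mode are detected via a dynamic-range
#' guard: when the log10 intensity range is below `minRangeLog10` (two
#' orders of magnitude by default, i.e. 20 dB) the estimate is flagged
#' degenerate and the minimum intensity is returned, so every frame ends
#' up non-silent.
#'
#' @param intensity non-negative per-frame intensity vector (at least 10
#'   frames).
#' @param nBins histogram resolution.
#' @param minRangeLog10 dynamic-range guard in log10 units.
#' @return Threshold on the intensity scale, with attribute `degenerate`
#'   (logical).
#' @export
estimateSilenceThreshold <- function(intensity, nBins = 256L,
                                     minRangeLog10 = 2) {
  assertThat(length(intensity) >= 10L, "need at least 10 frames")
  assertThat(all(intensity >= 0), "intensity must be non-negative")
  li <- log10(pmax(intensity, 1e-12))
  lo <- min(li)
  hi <- max(li)
  if (hi - lo < minRangeLog10) {
    return(structure(min(intensity), degenerate = TRUE))
  }
  breaks <- seq(lo, hi, length.out = nBins + 1L)
  counts <- tabulate(
    pmin(nBins, pmax(1L, findInterval(li, breaks, rightmost.closed = TRUE))),
    nBins
  )
  mids <- (breaks[-1] + breaks[-(nBins + 1L)]) / 2
  w <- counts / sum(counts)
  mu <- cumsum(w * mids)
  omega <- cumsum(w)
  muT <- mu[nBins]
  # between-class variance; maximize over split after bin k
  sigmaB <- (muT * omega - mu)^2 / pmax(omega * (1 - omega), 1e-12)
  sigmaB[omega <= 0 | omega >= 1] <- -Inf
  k <- which.max(sigmaB[-nBins])
  thrLog <- breaks[k + 1L]
  thr <- 10^thrLog
  # keep strictly inside the observed range
  thr <- min(max(thr, 10^lo * (1 + 1e-9)), 10^hi * (1 - 1e-9))
  structure(thr, degenerate = FALSE)
}

#' Silence detection configuration
#'
#' @param nBins histogram bins for the threshold estimate.
#' @param minRangeLog10 dynamic-range guard (log10 units).
#' @param closeGapS when positive, SIL gaps shorter than this many seconds
#'   are closed (morphological smoothing); default 0 = off.
#' @return A list of class `silenceConfig`.
#' @export
silenceConfig <- function(nBins = 256L, minRangeLog10 = 2, closeGapS = 0) {
  structure(
    list(nBins = as.integer(nBins), minRangeLog10 = minRangeLog10,
         closeGapS = closeGapS),
    class = "silenceConfig"
  )
}

#' Detect silence frames with a per-recording adaptive threshold
#'
#' Each frame's intensity is its mean-square energy; a frame is `SIL` iff
#' its intensity falls below the threshold from
#' [estimateSilenceThreshold()]. No temporal smoothing is applied unless
#' `closeGapS` is set in the config.
#'
#' @param rec an [AudioRecording-class].
#' @param grid a [FrameGrid-class].
#' @param config a [silenceConfig()].
#' @return A [SilenceResult-class].
#' @export
detectSilence <- function(rec, grid, config = silenceConfig()) {
  intensity <- frameIntensity(rec, grid)
  thr <- estimateSilenceThreshold(intensity,
    nBins = config$nBins, minRangeLog10 = config$minRangeLog10
  )
  deg <- isTRUE(attr(thr, "degenerate"))
  sil <- !deg & intensity < as.numeric(thr)
  if (config$closeGapS > 0) {
    maxGap <- floor(config$closeGapS / grid@windowS)
    r <- rle(sil)
    short <- r$values & r$lengths < maxGap
    # only close gaps strictly inside the stream
    if (length(r$values) > 2L) {
      inner <- seq_along(r$values) > 1L & seq_along(r$values) < length(r$values)
      r$values[short & inner] <- FALSE
    }
    sil <- inverse.rle(r)
  }
  new("SilenceResult",
    stream = labelStream(
      ifelse(sil, "SIL", "NONSIL"), ALPHABET_SILENCE, 1 / grid@windowS
    ),
    threshold = as.numeric(thr), degenerate = deg
  )
}

#' Per-frame intensity (mean-square energy)
#'
#' @param rec an [AudioRecording-class].
#' @param grid a [FrameGrid-class].
#' @return Numeric vector of `nFrames(grid)` intensities.
#' @export
frameIntensity <- function(rec, grid) {
  idx <- .frameSampleIndex(grid)
  spf <- idx$samplesPerFrame
  pick <- outer(0:(spf - 1L), idx$start, `+`)
  colMeans(matrix(samples(rec)[pick]^2, nrow = spf))
}
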