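# Short-term feature extraction: 36 features per non-overlapping 0.1 s
# window. Eight spectral/temporal descriptors, 13 MFCCs (Slaney-style mel
# filterbank + orthonormal DCT-II of the log filter outputs), 12 chroma
# bins folded onto pitch classes (A440 reference), harmonic ratio and
# fundamental frequency from the normalized autocorrelation, and HF500,
# the ratio of spectral power in (500, 3500] Hz to power in [80, 500] Hz.

#' Feature extraction configuration
#'
#' @param nMfcc number of cepstral coefficients (default 13).
#' @param nMelFilters number of triangular mel filters (default 40,
#'   Slaney-style construction: linear below 1 kHz, logarithmic above).
#' @param chromaRefHz chroma tuning reference (default A = 440 Hz).
#' @param hf500LowHz,hf500HighHz HF500 band edges; low band is inclusive
#'   `[80, 500]` Hz, high band `(500, 3500]` Hz, membership by bin center.
#' @param rolloffFraction spectral roll-off cumulative-power fraction.
#' @param energySubframes sub-blocks used for the entropy of energy.
#' @param f0RangeHz admissible fundamental frequency search range.
#' @param logFloor floor applied to log arguments and to the HF500
#'   denominator so silent frames yield finite features.
#' @return A list of class `featureConfig`.
#' @export
featureConfig <- function(nMfcc = 13L, nMelFilters = 40L, chromaRefHz = 440,
                          hf500LowHz = c(80, 500), hf500HighHz = c(500, 3500),
                          rolloffFraction = 0.90, energySubframes = 10L,
                          f0RangeHz = c(50, 1600), logFloor = 1e-10) {
  structure(
    list(
      nMfcc = as.integer(nMfcc), nMelFilters = as.integer(nMelFilters),
      chromaRefHz = chromaRefHz, hf500LowHz = hf500LowHz,
      hf500HighHz = hf500HighHz, rolloffFraction = rolloffFraction,
      energySubframes = as.integer(energySubframes),
      f0RangeHz = f0RangeHz, logFloor = logFloor
    ),
    class = "featureConfig"
  )
}

# ------------------------------------------------------------ primitives ----

.hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# Slaney-style mel scale: linear below 1 kHz, log-spaced above.
.hzToMel <- function(f) {
  ifelse(f < 1000, f * 3 / 200, 15 + log(pmax(f, 1000) / 1000) / log(6.4) * 27)
}

.melToHz <- function(m) {
  ifelse(m < 15, m * 200 / 3, 1000 * exp((m - 15) * log(6.4) / 27))
}

# nFilters x nBins filterbank matrix for one-sided spectra of a length-fftLen
# DFT (nBins = floor(fftLen/2) + 1), with Slaney area normalization.
.melFilterbank <- function(nFilters, fftLen, sampleRate) {
  nBins <- fftLen %/% 2L + 1L
  freqs <- (0:(nBins - 1)) * sampleRate / fftLen
  pts <- .melToHz(seq(.hzToMel(0), .hzToMel(sampleRate / 2),
    length.out = nFilters + 2
  ))
  fb <- matrix(0, nFilters, nBins)
  for (m in seq_len(nFilters)) {
    lo <- pts[m]; ce <- pts[m + 1]; hi <- pts[m + 2]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down)) * 2 / (hi - lo)
  }
  fb
}

# orthonormal DCT-II matrix, nCoef x m
.dctMatrix <- function(nCoef, m) {
  d <- matrix(0, nCoef, m)
  for (k in 0:(nCoef - 1)) {
    d[k + 1, ] <- cos(pi * k * (2 * (1:m) - 1) / (2 * m)) *
      if (k == 0) sqrt(1 / m) else sqrt(2 / m)
  }
  d
}

# ------------------------------------------------- single-spectrum ops ----

#' Mel-frequency cepstral coefficients of one power spectrum
#'
#' The one-sided power spectrum of a single frame is passed through a
#' Slaney-style mel filterbank; the first `nCoeffs` orthonormal DCT-II
#' coefficients of the log filter outputs (floored at `logFloor`) are
#' returned. An all-zero spectrum yields the finite log-floor cepstrum,
#' never `NaN`.
#'
#' @param powerSpectrum non-negative one-sided power spectrum
#'   (`floor(fftLen/2) + 1` bins, DC first).
#' @param sampleRate sample rate in Hz.
#' @param nCoeffs number of coefficients (default 13).
#' @param nFilters number of mel filters (default 40).
#' @param logFloor floor for the log argument.
#' @return Numeric vector of `nCoeffs` coefficients.
#' @export
computeMfcc <- function(powerSpectrum, sampleRate, nCoeffs = 13L,
                        nFilters = 40L, logFloor = 1e-10) {
  assertThat(all(powerSpectrum >= 0), "power spectrum must be non-negative")
  fftLen <- 2L * (length(powerSpectrum) - 1L)
  fb <- .melFilterbank(nFilters, fftLen, sampleRate)
  melE <- as.numeric(fb %*% powerSpectrum)
  d <- .dctMatrix(nCoeffs, nFilters)
  as.numeric(d %*% log(pmax(melE, logFloor)))
}

#' HF500: high-to-low spectral energy ratio
#'
#' Ratio of power summed over bins with center frequency in
#' `(500, 3500]` Hz to power in bins within `[80, 500]` Hz, a vocal-arousal
#' correlate. The denominator is floored at `eps` so that frames with no
#' low-band energy give a large finite value (and silent frames give 0).
#'
#' @inheritParams computeMfcc
#' @param lowHz inclusive low band, default `c(80, 500)`.
#' @param highHz half-open high band `(500, 3500]`, default `c(500, 3500)`.
#' @param eps denominator floor.
#' @return A single non-negative number.
#' @export
computeHf500 <- function(powerSpectrum, sampleRate, lowHz = c(80, 500),
                         highHz = c(500, 3500), eps = 1e-10) {
  if (sampleRate < 2 * highHz[2])
    stopValidation(sprintf(
      "sample rate %d too low for the %g Hz HF500 band", sampleRate, highHz[2]
    ))
  fftLen <- 2L * (length(powerSpectrum) - 1L)
  freqs <- (0:(length(powerSpectrum) - 1)) * sampleRate / fftLen
  lowMask <- freqs >= lowHz[1] & freqs <= lowHz[2]
  highMask <- freqs > highHz[1] & freqs <= highHz[2]
  sum(powerSpectrum[highMask]) / max(sum(powerSpectrum[lowMask]), eps)
}

#' Chroma vector of one power spectrum
#'
#' Spectral power is folded onto 12 pitch classes relative to the tuning
#' reference (class 1 = A at `refHz`), normalized to sum to 1 (all zeros
#' for a silent frame).
#'
#' @inheritParams computeMfcc
#' @param refHz tuning reference, default 440.
#' @return Numeric 12-vector.
#' @export
computeChroma <- function(powerSpectrum, sampleRate, refHz = 440) {
  fftLen <- 2L * (length(powerSpectrum) - 1L)
  freqs <- (0:(length(powerSpectrum) - 1)) * sampleRate / fftLen
  keep <- freqs > 0
  pc <- (round(12 * log2(freqs[keep] / refHz)) %% 12) + 1
  out <- vapply(1:12, function(c) sum(powerSpectrum[keep][pc == c]), numeric(1))
  tot <- sum(out)
  if (tot > 0) out / tot else out
}

# taper-compensated normalized autocorrelation over an admissible lag range
.pitchAutocorr <- function(frame, sampleRate, f0RangeHz = c(50, 1600)) {
  n <- length(frame)
  e0 <- sum(frame^2)
  if (e0 < 1e-20) return(list(hr = 0, f0 = 0))
  nfft <- 2^ceiling(log2(2 * n))
  sp <- fft(c(frame, rep(0, nfft - n)))
  ac <- Re(fft(Mod(sp)^2, inverse = TRUE)) / nfft
  lagMin <- max(2L, floor(sampleRate / f0RangeHz[2]))
  lagMax <- min(n - 2L, ceiling(sampleRate / f0RangeHz[1]))
  if (lagMax <= lagMin) return(list(hr = 0, f0 = 0))
  lags <- lagMin:lagMax
  rn <- ac[lags + 1L] / ac[1L] * n / (n - lags)   # compensate linear taper
  hr <- max(0, min(1, max(rn)))
  # the fundamental period is the *smallest* lag at the peak level: integer
  # multiples of the true period score equally high (subharmonic ambiguity)
  i <- which(rn >= max(rn) - 0.02 * max(max(rn), 0))[1]
  # parabolic interpolation around the peak for sub-sample lag accuracy
  lagStar <- lags[i]
  if (i > 1 && i < length(rn)) {
    a <- rn[i - 1]; b <- rn[i]; c <- rn[i + 1]
    den <- a - 2 * b + c
    if (abs(den) > 1e-12) lagStar <- lags[i] + 0.5 * (a - c) / den
  }
  list(hr = hr, f0 = sampleRate / lagStar)
}

#' Harmonic ratio and fundamental frequency of one frame
#'
#' The harmonic ratio is the maximum of the taper-compensated normalized
#' autocorrelation over the admissible pitch lag range; the fundamental
#' frequency is the frequency of that lag (parabolically interpolated).
#' Degenerate (all-zero) frames return 0 for both.
#'
#' @param frame raw (unwindowed) sample vector of one frame.
#' @param sampleRate sample rate in Hz.
#' @param f0RangeHz admissible f0 range, default `c(50, 1600)`.
#' @return A single number in `[0, 1]` ([computeHarmonicRatio()]) or an f0
#'   in Hz, 0 when degenerate ([computeF0()]).
#' @export
computeHarmonicRatio <- function(frame, sampleRate, f0RangeHz = c(50, 1600)) {
  .pitchAutocorr(frame, sampleRate, f0RangeHz)$hr
}

#' @rdname computeHarmonicRatio
#' @export
computeF0 <- function(frame, sampleRate, f0RangeHz = c(50, 1600)) {
  .pitchAutocorr(frame, sampleRate, f0RangeHz)$f0
}

# ------------------------------------------------------- full featurizer ----

#' Compute the 36-feature matrix of a recording
#'
#' Features are computed independently per frame of the grid (each frame's
#' DFT spans exactly that frame's samples, Hamming-windowed); spectral flux
#' of the first frame is defined as 0. See [FEATURE_NAMES] for the column
#' order.
#'
#' @param rec an [AudioRecording-class].
#' @param grid the [FrameGrid-class] derived from `rec`.
#' @param config a [featureConfig()].
#' @param chunkSize frames processed per vectorized block (memory knob).
#' @return A [FeatureMatrix-class] with `nFrames(grid)` rows.
#' @export
featurizeRecording <- function(rec, grid, config = featureConfig(),
                               chunkSize = 512L) {
  assertThat(is(rec, "AudioRecording"), "rec must be an AudioRecording")
  assertThat(is(grid, "FrameGrid"), "grid must be a FrameGrid")
  assertThat(grid@sampleRate == sampleRate(rec),
    "grid was not derived from this recording")

  fs <- sampleRate(rec)
  idx <- .frameSampleIndex(grid)
  spf <- idx$samplesPerFrame
  nf <- grid@nFrames
  nBins <- spf %/% 2L + 1L
  freqs <- (0:(nBins - 1)) * fs / spf
  win <- .hamming(spf)

  cfg <- config
  fb <- .melFilterbank(cfg$nMelFilters, spf, fs)
  dct <- .dctMatrix(cfg$nMfcc, cfg$nMelFilters)
  pcOfBin <- c(NA, (round(12 * log2(freqs[-1] / cfg$chromaRefHz)) %% 12) + 1)
  lowMask <- freqs >= cfg$hf500LowHz[1] & freqs <= cfg$hf500LowHz[2]
  highMask <- freqs > cfg$hf500HighHz[1] & freqs <= cfg$hf500HighHz[2]
  if (fs < 2 * cfg$hf500HighHz[2])
    stopValidation("sample rate too low for the HF500 high band")

  nSub <- cfg$energySubframes
  subLen <- spf %/% nSub

  out <- matrix(0, nf, length(FEATURE_NAMES),
    dimnames = list(NULL, FEATURE_NAMES)
  )
  prevNormP <- NULL # last normalized power spectrum of the previous chunk

  nfftAc <- 2^ceiling(log2(2 * spf))
  lagMin <- max(2L, floor(fs / cfg$f0RangeHz[2]))
  lagMax <- min(spf - 2L, ceiling(fs / cfg$f0RangeHz[1]))
  lags <- lagMin:lagMax
  taper <- spf / (spf - lags)

  for (chunkStart in seq(1L, nf, by = chunkSize)) {
    cols <- chunkStart:min(nf, chunkStart + chunkSize - 1L)
    m <- length(cols)
    pick <- outer(0:(spf - 1L), idx$start[cols], `+`)
    fr <- matrix(samples(rec)[pick], nrow = spf)

    # --- time-domain features
    energy <- colMeans(fr^2)
    sgn <- fr >= 0
    zcr <- colSums(sgn[-1L, , drop = FALSE] != sgn[-spf, , drop = FALSE]) /
      (spf - 1L)
    subE <- matrix(
      colSums(matrix(fr[seq_len(subLen * nSub), ]^2, nrow = subLen)),
      nrow = nSub
    )
    subTot <- colSums(subE)
    pSub <- sweep(subE, 2, pmax(subTot, cfg$logFloor), "/")
    entE <- -colSums(ifelse(pSub > 0, pSub * log2(pSub), 0))
    entE[subTot <= cfg$logFloor] <- 0

    # --- spectra (Hamming window, one-sided)
    sp <- mvfft(fr * win)[seq_len(nBins), , drop = FALSE]
    mag <- Mod(sp)
    pw <- mag^2

    magTot <- colSums(mag)
    cen <- colSums(freqs * mag) / pmax(magTot, cfg$logFloor)
    cen[magTot <= cfg$logFloor] <- 0
    spread <- sqrt(
      colSums((outer(freqs, cen, `-`))^2 * mag) / pmax(magTot, cfg$logFloor)
    )
    spread[magTot <= cfg$logFloor] <- 0

    pwTot <- colSums(pw)
    normP <- sweep(pw, 2, pmax(pwTot, cfg$logFloor), "/")
    ent <- -colSums(ifelse(normP > 0, normP * log(normP), 0)) / log(nBins)
    ent[pwTot <= cfg$logFloor] <- 0

    flux <- c(
      if (is.null(prevNormP)) 0 else sum((normP[, 1L] - prevNormP)^2),
      if (m > 1L) {
        colSums((normP[, -1L, drop = FALSE] - normP[, -m, drop = FALSE])^2)
      }
    )
    prevNormP <- normP[, m]

    cum <- apply(normP, 2L, cumsum)
    roll <- apply(cum >= cfg$rolloffFraction, 2L, function(z) which(z)[1]) / nBins
    roll[is.na(roll)] <- 0 # silent frame: no power to roll off

    # --- MFCC, chroma, HF500 (matrix forms)
    melE <- fb %*% pw
    mf <- t(dct %*% log(pmax(melE, cfg$logFloor)))
    chroma <- matrix(0, m, 12L)
    for (c in 1:12) {
      chroma[, c] <- colSums(pw[which(pcOfBin == c), , drop = FALSE])
    }
    chroma <- chroma / pmax(rowSums(chroma), cfg$logFloor)
    hf <- colSums(pw[highMask, , drop = FALSE]) /
      pmax(colSums(pw[lowMask, , drop = FALSE]), cfg$logFloor)

    # --- autocorrelation pitch features
    spAc <- mvfft(rbind(fr, matrix(0, nfftAc - spf, m)))
    ac <- Re(mvfft(Mod(spAc)^2, inverse = TRUE)) / nfftAc
    r0 <- ac[1L, ]
    hr <- numeric(m)
    f0 <- numeric(m)
    live <- r0 > 1e-20
    if (any(live)) {
      rn <- sweep(ac[lags + 1L, live, drop = FALSE], 2L, r0[live], "/") * taper
      colMax <- apply(rn, 2L, max)
      # smallest lag at the peak level: avoids subharmonic (period-multiple)
      # picks, which score identically under taper compensation
      iMax <- vapply(
        seq_len(ncol(rn)),
        function(j) which(rn[, j] >= colMax[j] - 0.02 * max(colMax[j], 0))[1],
        integer(1)
      )
      hrLive <- pmin(1, pmax(0, colMax))
      lagStar <- lags[iMax]
      inner <- iMax > 1L & iMax < length(lags)
      if (any(inner)) {
        ji <- which(inner)
        a <- rn[cbind(iMax[ji] - 1L, ji)]
        b <- rn[cbind(iMax[ji], ji)]
        cc <- rn[cbind(iMax[ji] + 1L, ji)]
        den <- a - 2 * b + cc
        adj <- ifelse(abs(den) > 1e-12, 0.5 * (a - cc) / den, 0)
        lagStar[ji] <- lags[iMax[ji]] + adj
      }
      hr[live] <- hrLive
      f0[live] <- fs / lagStar
    }

    out[cols, ] <- cbind(
      energy, zcr, entE, cen, spread, ent, flux, roll,
      mf, chroma, hr, f0, hf
    )
  }

  new("FeatureMatrix",
    values = out, windowS = grid@windowS, sourceId = sourceId(rec)
  )
}

#' Persist / load a feature matrix as CSV
#'
#' @param fm a [FeatureMatrix-class].
#' @param path CSV path.
#' @param windowS,sourceId metadata to attach on read.
#' @return [readFeatureCsv()] returns a [FeatureMatrix-class].
#' @export
writeFeatureCsv <- function(fm, path) {
  write.csv(as.data.frame(featureValues(fm)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCsv
#' @export
readFeatureCsv <- function(path, windowS = 0.1, sourceId = "recording") {
  if (!file.exists(path)) stopIO(sprintf("feature CSV not found: %s", path))
  vals <- as.matrix(read.csv(path, check.names = FALSE))
  new("FeatureMatrix", values = vals, windowS = windowS, sourceId = sourceId)
}
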