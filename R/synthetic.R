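# Synthetic dyadic dialogue generator. Stands in for corpus material built
# by sequentially arranging spoken parts of two distinct voices with
# silences in between, and emits frame-accurate ground truth at 100
# frames/s. Voices are seeded harmonic complexes (no external assets); the
# f0 gap between the two voices is the difficulty knob that emulates
# different-sex (large gap) vs same-sex (small gap) dyads.

# evaluate code under a temporary RNG state
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Specify a synthetic voice
#'
#' A voice is a harmonic complex at fundamental `f0Hz` with geometrically
#' decaying harmonics shaped by Gaussian formant bumps. `jitterPct`
#' controls both an utterance-level f0 offset and a slow intra-utterance
#' f0 modulation (log-normal, so prosodic variation across utterances
#' overlaps between voices with nearby f0, which keeps small f0 gaps
#' genuinely hard).
#'
#' @param f0Hz fundamental frequency (e.g. 110 for a low voice, 210 for a
#'   high one).
#' @param nHarmonics number of harmonics (capped at 0.45 * sampleRate).
#' @param harmonicDecay per-harmonic amplitude factor.
#' @param formantCentersHz formant center frequencies.
#' @param jitterPct f0 perturbation scale in percent (default 10).
#' @param amplitude target RMS of an utterance (default 0.1).
#' @return A list of class `VoiceSpec`.
#' @export
voiceSpec <- function(f0Hz = 110, nHarmonics = 25L, harmonicDecay = 0.6,
                      formantCentersHz = c(500, 1500, 2500),
                      jitterPct = 10, amplitude = 0.1) {
  assertThat(f0Hz > 0, "f0Hz must be positive")
  assertThat(amplitude > 0, "amplitude must be positive")
  structure(
    list(
      f0Hz = f0Hz, nHarmonics = as.integer(nHarmonics),
      harmonicDecay = harmonicDecay, formantCentersHz = formantCentersHz,
      jitterPct = jitterPct, amplitude = amplitude
    ),
    class = "VoiceSpec"
  )
}

#' Specify a synthetic dialogue
#'
#' Utterances are placed sequentially (never overlapping) with silences in
#' between; speakers alternate, keeping the floor with probability
#' `pHold`. The noise floor is white noise at `noiseFloorDb` dB relative
#' to the speech RMS target, which puts silent-frame energies around
#' 1e-7 against speech-frame energies around 1e-2 at the defaults.
#'
#' @param durationS total dialogue length in seconds.
#' @param uttRangeS `c(min, max)` utterance length, sampled uniformly.
#' @param silRangeS `c(min, max)` inter-utterance silence, sampled
#'   uniformly.
#' @param pHold probability that the same speaker keeps the floor.
#' @param noiseFloorDb noise floor in dB relative to speech RMS.
#' @param sampleRate sample rate in Hz.
#' @param seed integer seed; the build is bit-reproducible given it.
#' @return A list of class `DialogueSpec`.
#' @export
dialogueSpec <- function(durationS = 300, uttRangeS = c(1, 3),
                         silRangeS = c(0.5, 1.5), pHold = 0.15,
                         noiseFloorDb = -50, sampleRate = 16000L,
                         seed = 1L) {
  assertThat(durationS > 0, "durationS must be positive")
  assertThat(uttRangeS[1] > 0 && uttRangeS[2] >= uttRangeS[1],
    "invalid utterance length range")
  structure(
    list(
      durationS = durationS, uttRangeS = uttRangeS, silRangeS = silRangeS,
      pHold = pHold, noiseFloorDb = noiseFloorDb,
      sampleRate = as.integer(sampleRate), seed = as.integer(seed)
    ),
    class = "DialogueSpec"
  )
}

#' Synthesize one utterance of a voice
#'
#' Harmonic complex at the (jittered) fundamental with decaying,
#' formant-shaped harmonics and random phases; 10 ms raised-cosine edge
#' ramps avoid clicks; the result is RMS-normalized to the voice's
#' amplitude before ramping. Deterministic given `seed`; with `seed =
#' NULL` the current RNG state is consumed.
#'
#' @param v a [voiceSpec()].
#' @param lengthS utterance length in seconds.
#' @param sampleRate sample rate in Hz.
#' @param seed optional integer seed.
#' @return Numeric sample vector of `round(lengthS * sampleRate)` samples.
#' @export
synthVoiceUtterance <- function(v, lengthS, sampleRate, seed = NULL) {
  assertThat(inherits(v, "VoiceSpec"), "v must be a VoiceSpec")
  assertThat(lengthS > 0, "lengthS must be positive")
  .withSeed(seed, {
    fs <- sampleRate
    n <- round(lengthS * fs)
    jit <- v$jitterPct / 100

    # utterance-level f0 offset + slow intra-utterance modulation
    # (control points every 0.3 s: prosodic drift, not vibrato — pitch must
    # stay locally periodic over one 0.1 s analysis window)
    scale0 <- exp(rnorm(1, 0, jit))
    nCtl <- max(2L, ceiling(lengthS / 0.3))
    ctl <- rnorm(nCtl, 0, jit)
    mod <- approx(seq(0, n - 1, length.out = nCtl), ctl, xout = 0:(n - 1))$y
    f0t <- v$f0Hz * scale0 * exp(mod)

    nh <- min(v$nHarmonics, floor(0.45 * fs / max(f0t)))
    nh <- max(1L, nh)
    phase <- 2 * pi * cumsum(f0t) / fs
    gains <- v$harmonicDecay^(0:(nh - 1)) *
      .formantGain((1:nh) * v$f0Hz * scale0, v$formantCentersHz)
    phi <- runif(nh, 0, 2 * pi)

    x <- numeric(n)
    for (h in seq_len(nh)) {
      x <- x + gains[h] * sin(h * phase + phi[h])
    }
    x <- x * v$amplitude / max(sqrt(mean(x^2)), 1e-12)

    ramp <- min(n %/% 2L, round(0.01 * fs))
    if (ramp > 0) {
      env <- 0.5 * (1 - cos(pi * (1:ramp) / ramp))
      x[1:ramp] <- x[1:ramp] * env
      x[(n - ramp + 1):n] <- x[(n - ramp + 1):n] * rev(env)
    }
    x
  })
}

# Gaussian formant bumps over a gentle floor; bandwidth widens with center
# frequency as in natural vowels.
.formantGain <- function(freqHz, centers) {
  g <- rep(0.3, length(freqHz))
  for (fc in centers) {
    bw <- min(250, max(80, 0.18 * fc))
    g <- g + exp(-0.5 * ((freqHz - fc) / bw)^2)
  }
  g
}

#' Build a complete synthetic dialogue
#'
#' Places alternating utterances of the two voices with sampled silences,
#' adds the white-noise floor, and returns the recording together with the
#' utterance annotation and the 100 frames/s ground-truth stream (a 10 ms
#' truth frame is `P1`/`P2` iff it lies entirely inside an utterance).
#'
#' @param v1,v2 [voiceSpec()]s for person 1 and person 2.
#' @param d a [dialogueSpec()].
#' @param sourceId identifier for the generated recording.
#' @return A [SyntheticDialogue-class].
#' @export
buildDialogue <- function(v1, v2, d, sourceId = sprintf("dyad-seed%d", d$seed)) {
  assertThat(inherits(d, "DialogueSpec"), "d must be a DialogueSpec")
  .withSeed(d$seed, {
    fs <- d$sampleRate
    nTotal <- round(d$durationS * fs)

    startS <- numeric(0)
    stopS <- numeric(0)
    who <- character(0)
    t <- runif(1, d$silRangeS[1], d$silRangeS[2])
    spk <- sample(ALPHABET_SPEAKER, 1)
    repeat {
      len <- runif(1, d$uttRangeS[1], d$uttRangeS[2])
      if (t + len > d$durationS - 1e-3) break
      startS <- c(startS, t)
      stopS <- c(stopS, t + len)
      who <- c(who, spk)
      t <- t + len + runif(1, d$silRangeS[1], d$silRangeS[2])
      if (runif(1) >= d$pHold) spk <- setdiff(ALPHABET_SPEAKER, spk)
    }
    if (!all(ALPHABET_SPEAKER %in% who))
      stopValidation("dialogue too short to give both speakers an utterance")

    noiseRms <- (v1$amplitude + v2$amplitude) / 2 * 10^(d$noiseFloorDb / 20)
    x <- rnorm(nTotal, 0, noiseRms)

    # snap utterances to the sample grid so annotation and audio agree
    for (i in seq_along(startS)) {
      s0 <- round(startS[i] * fs)
      v <- if (who[i] == "P1") v1 else v2
      u <- synthVoiceUtterance(v, stopS[i] - startS[i], fs)
      ix <- (s0 + 1):(s0 + length(u))
      x[ix] <- x[ix] + u
      startS[i] <- s0 / fs
      stopS[i] <- (s0 + length(u)) / fs
    }
    x <- pmin(1, pmax(-1, x))

    rec <- audioRecording(x, fs, sourceId)
    ann <- annotation(startS, stopS, who)
    truthGrid <- new("FrameGrid",
      windowS = 0.01, nFrames = as.integer(floor(d$durationS / 0.01 + 1e-9)),
      sampleRate = fs
    )
    truth <- annotationToStream(ann, truthGrid)
    truth@frameRate <- 100

    new("SyntheticDialogue",
      recording = rec, truth = truth, annotation = ann,
      voiceSpecs = list(P1 = v1, P2 = v2), dialogueSpec = unclass(d)
    )
  })
}

#' Build a corpus of synthetic dyads across a voice-separation grid
#'
#' Dyads cycle through the `(f0_1, f0_2)` pairs of `separationGrid`, from
#' easy (large f0 gap, the different-sex analogue) to hard (small gap,
#' same-sex analogue). Each dyad gets its own seed derived from the master
#' seed; the manifest records pairings and seeds so any dyad can be
#' regenerated independently with [buildDialogue()].
#'
#' @param nDyads number of dyads (>= 1).
#' @param separationGrid list of `c(f0_1, f0_2)` pairs.
#' @param baseSpec the [dialogueSpec()] shared by all dyads (its seed is
#'   replaced per dyad).
#' @param seed master seed.
#' @param materialize build the audio now (`TRUE`, default) or return only
#'   the manifest (`FALSE`; saves memory for large corpora).
#' @return A list with `dialogues` (list of [SyntheticDialogue-class], or
#'   `NULL`s when not materialized) and `manifest` (data.frame with
#'   dyad_id, f0_1, f0_2, gap, seed).
#' @export
buildCorpus <- function(nDyads, separationGrid = list(
                          c(110, 210), c(110, 160), c(110, 120)
                        ),
                        baseSpec = dialogueSpec(), seed = 1L,
                        materialize = TRUE) {
  assertThat(nDyads >= 1, "nDyads must be at least 1")
  seeds <- .withSeed(seed, sample.int(.Machine$integer.max - 1L, nDyads))
  pairIdx <- rep(seq_along(separationGrid), length.out = nDyads)
  manifest <- data.frame(
    dyad_id = sprintf("dyad%02d", seq_len(nDyads)),
    f0_1 = vapply(separationGrid[pairIdx], `[`, numeric(1), 1),
    f0_2 = vapply(separationGrid[pairIdx], `[`, numeric(1), 2),
    seed = seeds
  )
  manifest$gap <- abs(manifest$f0_2 - manifest$f0_1)
  dialogues <- lapply(seq_len(nDyads), function(i) {
    if (!materialize) return(NULL)
    corpusDialogue(manifest[i, ], baseSpec)
  })
  list(dialogues = dialogues, manifest = manifest)
}

#' Regenerate one corpus dyad from a manifest row
#'
#' @param manifestRow one row of the manifest from [buildCorpus()].
#' @param baseSpec the corpus [dialogueSpec()].
#' @return A [SyntheticDialogue-class].
#' @export
corpusDialogue <- function(manifestRow, baseSpec = dialogueSpec()) {
  d <- baseSpec
  d$seed <- as.integer(manifestRow$seed)
  buildDialogue(
    voiceSpec(f0Hz = manifestRow$f0_1),
    voiceSpec(f0Hz = manifestRow$f0_2),
    d, sourceId = as.character(manifestRow$dyad_id)
  )
}
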