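# Shared fixtures, all built in code at test time.

sineRecording <- function(freqHz, durS, fs = 16000L, amp = 0.5,
                          id = "tone") {
  n <- round(durS * fs)
  audioRecording(amp * sin(2 * pi * freqHz * (0:(n - 1)) / fs), fs, id)
}

makeGrid <- function(durS, windowS = 0.1, fs = 16000L) {
  new("FrameGrid",
    windowS = windowS, nFrames = as.integer(floor(durS / windowS + 1e-9)),
    sampleRate = as.integer(fs)
  )
}

# feature matrix with the canonical schema but arbitrary values
fakeFeatures <- function(nFrames, windowS = 0.1, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(nFrames * length(FEATURE_NAMES)), nFrames,
    dimnames = list(NULL, FEATURE_NAMES)
  )
  new("FeatureMatrix", values = vals, windowS = windowS, sourceId = "fake")
}

# one-sided power spectrum of a Hamming-windowed frame
framePowerSpectrum <- function(frame) {
  n <- length(frame)
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  Mod(fft(frame * win)[seq_len(n %/% 2 + 1)])^2
}

# lazily-built end-to-end run of one easy dyad, shared across test files
.fixtureCache <- new.env(parent = emptyenv())

easyDyadRun <- function() {
  if (is.null(.fixtureCache$easy)) {
    d <- buildDialogue(
      voiceSpec(f0Hz = 110), voiceSpec(f0Hz = 210),
      dialogueSpec(durationS = 250, seed = 401)
    )
    cfg <- pipelineConfig(
      learnSpan = c(0, 120), testSpan = c(120, 240), seed = 401
    )
    res <- suppressMessages(runDyad(d@recording, d@annotation, cfg,
      truth = d@truth
    ))
    .fixtureCache$easy <- list(dialogue = d, config = cfg, run = res)
  }
  .fixtureCache$easy
}
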