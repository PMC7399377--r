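Package: dyadiar
Title: Supervised Speaker Diarization for Dyadic Conversations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Supervised speaker diarization ("who speaks when") for
    two-person conversations recorded with a single microphone, aimed at
    psychotherapy process research and similar dyadic settings. A short
    human-annotated learning segment is used to train one random-forest
    classifier per dyad on 36 short-term audio features (energy, spectral
    shape, MFCCs, chroma, harmonicity, fundamental frequency and the
    HF500 vocal-arousal ratio) computed in non-overlapping 0.1 s windows.
    Per-recording adaptive silence detection and a pluggable voice
    activity detector are aggregated with the classifier output into a
    non-speech/person-1/person-2 stream. The out-of-bag error of each
    dyad's forest serves as a built-in quality estimate. Includes
    diarization error rate (DER) scoring with transitional-window
    exclusion, and a seeded synthetic dialogue generator with
    frame-accurate ground truth for desk-scale validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'conditions.R'
    'AllClasses.R'
    'RcppExports.R'
    'wav.R'
    'frames.R'
    'formats.R'
    'features.R'
    'silence.R'
    'vad.R'
    'classifier.R'
    'aggregation.R'
    'evaluation.R'
    'synthetic.R'
    'pipeline.R'
    'dyadiar-package.R'
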