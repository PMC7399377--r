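---
title: "Supervised dyadic diarization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised dyadic diarization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical procedure `dyadiar` implements,
the assumptions behind it, the tunable parameters that matter, what the
synthetic validation does and does not establish, and the numerical and
design choices made where the method left room for them.

## The model

Diarization here is framed as per-window supervised classification.
The dyadic setting justifies two strong simplifications:

* **The number of speakers is known (two).** The classifier output
  alphabet is fixed; there is no clustering and no speaker-count
  estimation.
* **Classifiers need not generalize across dyads.** One forest is
  trained per dyad, specialized to the two voices at hand, from a short
  human-annotated learning segment of that same recording session. This
  turns an open-set problem into a closed two-class one, which is why a
  comparatively simple learner achieves low error.

Each 0.1 s window is represented by 36 features. MFCCs carry most of
the speaker identity; the chroma vector, harmonic ratio and fundamental
frequency add pitch information (helpful when voices differ mainly in
f0); energy, zero-crossing rate, entropy of energy and the spectral
shape statistics separate speech from silence-like content; HF500 (the
high/low spectral energy ratio) is a vocal-arousal correlate kept in the
schema both for classification and for downstream process research.
No feature standardization is applied: forests are invariant to monotone
per-feature rescaling, and keeping raw units makes feature matrices
interpretable and cacheable.

The forest follows Breiman's algorithm: 500 trees, each grown to purity
on an n-of-n bootstrap of the learning frames, choosing at every split
the best of `floor(sqrt(36)) = 6` randomly drawn features by Gini
impurity. Classification is the majority vote. The **out-of-bag (OOB)
error** — each learning frame judged only by trees whose bootstrap
missed it — is computed entirely within the learning set and is exposed
as the model's generalization estimate; its correlation with the speaker
error measured on held-out data is the property that makes it usable as
a per-dyad quality check without a second annotation pass.

Only *speech* frames enter the learning set (frames fully covered by an
annotated utterance); the classifier never sees a "silence" class and
will therefore emit a speaker label on every frame. Three streams are
merged to the final decision, in strict precedence: frames below the
silence threshold are non-speech regardless of anything else; surviving
frames that the voice activity detector (VAD) calls unvoiced are
non-speech (noise); only the rest take the classifier's label.

## Tunable parameters

| Parameter | Default | Units | Why this default |
|---|---|---|---|
| `windowS` | 0.1 | s | The analysis resolution of the whole method: features, streams and predictions all live on this grid. Fine enough for turn-taking analysis, coarse enough for stable spectra. |
| `nTrees` | 500 | trees | Large enough that OOB estimates are stable; error plateaus well before this. |
| `mtry` | 6 | features | `floor(sqrt(p))`, the standard classification default. |
| `learnSpan` | 0–600 | s | Ten annotated minutes yields roughly 4–5 min of speech per speaker under typical turn-taking, comfortably above the ~100-frame floor the package enforces. |
| `nMelFilters` | 40 | filters | Slaney-style bank (linear below 1 kHz, log above); 40 is the conventional size for 13 cepstra. |
| `hf500` bands | [80, 500] / (500, 3500] | Hz | Fixed by the definition of the measure; bin membership by center frequency. |
| `f0RangeHz` | 50–1600 | Hz | Generous around the speech range so tones used in validation are also resolvable. |
| `silence minRangeLog10` | 2 | log10 units | A recording whose frame energies span less than 20 dB has no silence mode; see below. |
| VAD `threshold` | 0.5 | score | Decision point of the default harmonicity/flatness rule, calibrated on the package's synthetic material only. |

## Silence detection

The per-recording threshold is an Otsu split: the per-frame log10
mean-square energy is histogrammed (256 bins) and the cut maximizing
between-class variance is chosen, then mapped back to the energy scale.
Working in log energy makes the estimate gain-invariant — scaling the
recording by *c* scales the threshold by *c²* and leaves the
`SIL`/`NONSIL` stream unchanged — which matters because session
recordings are not level-normalized.

Otsu always returns *some* split, so a guard is needed for recordings
with no silence at all (e.g. a continuous tone): when the observed
log-energy range is under `minRangeLog10 = 2` (20 dB), the detector
declares the estimate degenerate and labels everything `NONSIL`. Real
silence-versus-speech contrasts span several orders of magnitude, so
20 dB is conservative in both directions.

The VAD is deliberately a plug-in contract: production users may have a
stronger external detector (the aggregation rules do not care where the
`VOICED`/`UNVOICED` stream came from). The default detector scores
`0.6·harmonic_ratio + 0.4·(1 − spectral_entropy)` against 0.5 — voiced
speech is harmonic and spectrally peaked, noise is neither. It is
calibrated only on this package's synthetic fixtures and is not claimed
to be competitive on naturalistic noise. One ambiguity was resolved
here: the VAD runs over *all* frames, not only non-silent ones, and the
aggregation rules give silence precedence; running it only on non-silent
windows would produce the identical final stream, so the choice is
harmless and simpler.

## Evaluation

DER is reported as SpE + MSp + FASp, all percentages of the *scored*
summarized frames. Two choices deserve note:

* **Denominator.** All non-excluded summarized frames (speech and
  non-speech) form the denominator. This makes the three components
  additive to the reported DER and makes "DER = 100 − accuracy" hold
  exactly, at the cost of SpE being diluted by the non-speech fraction.
  The identical-voices check in the test suite therefore measures
  speaker confusion *on speech frames* where a 50% rate is the natural
  chance level.
* **Transitional exclusion, no collar.** Reference labels at 100
  frames/s are summarized 10-to-1; blocks containing more than one label
  are excluded from scoring. This is the boundary-forgiveness mechanism
  — no additional collar is applied (a configurable collar exists in the
  scoring call but defaults to 0, and the exclusion already removes
  every block containing a turn boundary).
* **Fixed speaker mapping.** Supervision fixes which speaker is `P1`;
  scoring never optimally relabels speakers, unlike unsupervised DER
  protocols. A model that swaps the speakers scores 100% SpE, as it
  should in this setting.

## The synthetic generator: what it emulates, what it does not

`buildDialogue` emulates labelled corpus construction by sequential
arrangement: utterances of two voices alternate (probability `pHold =
0.15` of keeping the floor) with uniform 1–3 s utterance lengths and
0.5–1.5 s gaps, no overlap, at 16 kHz. Ground truth is emitted at 100
frames/s, with a 10 ms frame labelled as a speaker iff it lies entirely
inside an utterance — the same containment convention the learning-set
builder uses at 0.1 s, which guarantees truth and learning labels can
never contradict outside transitional blocks.

Voices are harmonic complexes: geometrically decaying harmonics
(`harmonicDecay = 0.6`) shaped by Gaussian formant bumps at 500/1500/
2500 Hz over a 0.3 floor (so the fundamental remains the dominant
partial for low voices), random phases, 10 ms edge ramps, RMS 0.1.
`jitterPct = 10` applies a log-normal utterance-level f0 offset plus a
slow intra-utterance drift with control points every 0.3 s — prosodic
drift, deliberately slow so pitch stays locally periodic within one
0.1 s analysis window, but large enough that the f0 distributions of two
voices 10 Hz apart overlap heavily. That overlap is the point: the f0
gap becomes a graded difficulty knob (100 Hz ≈ different-sex easy case,
10 Hz ≈ same-sex hard case, 0 Hz = indistinguishable-by-construction
chance-level case). The noise floor is white at −50 dB relative to
speech RMS, putting silent-frame energies near 1e−7 against speech
frames near 1e−2.

What a green synthetic test establishes: the pipeline's plumbing,
determinism, the scoring arithmetic, the qualitative OOB↔error
relationship, and graded degradation with voice similarity. What it
does **not** establish: performance on real speech. Harmonic complexes
have no consonants, no amplitude dynamics within utterances, no channel
or room effects, and their silence/speech contrast is cleaner than
naturalistic audio; absolute error rates on real sessions will be
higher, and the VAD in particular is untested against real noise.
Dialogues for testing are generated at 4–6 minutes (2-minute learning
and test spans) rather than full session length, purely to keep the
suite fast; the protocol (first segment annotated, next segment scored)
is the same as at full scale.

## Numerical choices and degenerate inputs

* **Log floors.** All log arguments (mel filter outputs, silence
  intensities) and the HF500 denominator are floored at 1e−10, so silent
  frames yield finite features: energy 0, MFCCs at the floor cepstrum,
  chroma all-zero, HF500 0, harmonic ratio and f0 both 0. The feature
  matrix never contains NaN/Inf by construction (validity-checked).
* **Frame convention.** 0-based, half-open `[k·w, (k+1)·w)`; a trailing
  partial window is dropped. Frames only partially covered by an
  utterance are *not* taught to the classifier (conservative: never
  learn from mixed frames).
* **Subharmonic tie-break.** After taper compensation, the normalized
  autocorrelation scores every integer multiple of the true pitch period
  equally; f0 therefore takes the *smallest* lag within 2% of the peak,
  with parabolic interpolation for sub-sample accuracy. The harmonic
  ratio keeps the global maximum.
* **Vote ties.** With an even ensemble a 250–250 vote is possible; ties
  break deterministically toward `P1` (the lexicographically smaller
  label). The same rule applies to OOB voting and leaf majorities.
* **Spectral flux at frame 0** is defined as 0; it is the only feature
  that is not frame-local (tested as such).
* **Degenerate learning sets** (all features constant) refuse to train
  with a validation error rather than producing a vacuous forest.

## Open design decisions

* **Bagging with replacement.** The surrounding literature describes
  bagging both as sampling with and without replacement; the n-of-n
  with-replacement bootstrap is used by default because the OOB
  construction (≈36.8% of frames out of bag per tree) depends on it.
  A without-replacement mode (0.632·n subsampling) is exposed via
  `bagMode = "subsample"` for comparison.
* **"Two spectral centroids"** are implemented as the centroid and the
  spread (the first two moments of the magnitude spectrum), the pair
  conventionally returned together by short-term analysis libraries.
* **Hamming windowing** before the DFT follows common short-term
  analysis practice; the choice is not critical for any downstream
  decision and is fixed rather than exposed.
* **Sample rates** are accepted as-is (≥ 8 kHz; ≥ 7 kHz is required for
  the HF500 high band). The synthetic corpus uses 16 kHz as a realistic
  default for modern session recorders.
* **CLI as a thin layer.** All subcommands call exported functions and
  add only argument parsing and exit-code mapping (0 success, 2
  validation, 3 I/O), so everything the CLI does is testable through
  the package API.

## Known limitations

* Two speakers, non-overlapping speech only. Overlap is neither
  generated nor scored (the overlap DER term is structurally 0 here).
* The OOB error estimates *speaker* error; it says nothing about missed
  or false-alarm speech, which are governed by the silence/VAD stages.
* The default VAD is a fixture-calibrated stand-in, not a
  production-grade detector.
* Class imbalance in the learning set is not reweighted; with grossly
  asymmetric speech shares, the majority speaker dominates ties.
* Threshold estimation assumes a bimodal intensity histogram; recordings
  with dense low-level background chatter may split poorly.
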