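---
title: "Scoring REM sleep without atonia from surface EMG"
author: "rswaScoreR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring REM sleep without atonia from surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rswaScoreR)
```

## The problem

During healthy REM sleep, skeletal muscles are atonic. In REM sleep
behaviour disorder (RBD) this atonia fails, and patients enact their
dreams; quantifying the residual EMG activity — REM sleep without atonia
(RSWA) — is the key polysomnographic marker for RBD and a candidate
prodromal marker for alpha-synucleinopathies. The SINBAR (Sleep
Innsbruck–Barcelona) scoring scheme is the visual standard: it scores chin
(mentalis), forearm (flexor digitorum superficialis, FDS) and lower-leg
(tibialis anterior) surface EMG, epoch by epoch. Visual scoring is slow
and scorer-dependent; this package automates it.

The scorer takes an EDF recording with one or more EMG channels, a
standard 30-s hypnogram, and plain-text event lists (arousals required,
respiratory and snore events optional), and returns per-channel and
combined-channel RSWA metrics together with an exact event timestamp
table.

## The scoring model

All rule constants live in one validated object, `detectionParams()`; the
defaults below are the reference values of the scheme.

1. **Working rate.** EMG is resampled to 256 Hz by cubic-spline
   interpolation (`fsTarget`). Resampling at the native rate is the
   identity.
2. **REM segmentation.** Maximal runs of contiguous REM epochs form
   segments. A segment with at least 150 s of continuous REM
   (`minRemPeriod`) is a *REM period*; shorter runs are *REM bouts*.
3. **Artefact masking.** Arousal and respiratory events are excluded on
   all channels; snore intervals only on the mentalis, which the snoring
   vibration contaminates. Stretches whose 30 s rolling RMS falls below
   0.05 mV (`detachmentRms`) are treated as electrode detachment and
   excluded everywhere. Masks live on the scorer's 15 ms grid; an event
   partially covering a grid cell masks the whole cell.
4. **Baseline amplitude.** Each REM period is assigned the minimum RMS
   over all continuously artefact-free 30 s rolling windows inside it
   (`baselineWindow`, stepped on the 15 ms grid). If no clean 30 s window
   exists the search repeats at 15 s (`baselineWindowFallback`); failing
   that, the period inherits the baseline of the previous period with a
   measured value, or of the following one if none precedes. REM bouts
   take the baseline of the nearest period (midpoint distance, ties to
   the earlier period). A channel with no measurable baseline anywhere is
   discarded with a structured warning.
5. **Activity detection.** The RMS of the signal is computed in 30 ms
   windows (`rmsWindow`) stepped by 15 ms (`rmsStep`). A window whose RMS
   *strictly exceeds* twice the baseline (`thresholdFactor`) is an
   activity bout. Connected bouts spanning more than 0.1 s (`minBout`)
   seed an event; neighbouring bouts are absorbed while the
   sub-threshold interruption is shorter than 0.25 s (`maxGap`),
   iterating to a fixed point. An interruption of at least 0.25 s
   terminates the event.
6. **Classification.** Events of 0.1–5.0 s are *phasic*, events above
   5.0 s up to 15 s are *intermediate*. A 30-s REM epoch whose
   increased-activity coverage reaches 50% (15.0 s, inclusive) is
   *tonic*; its baseline is then elevated to the RMS of the signal over
   the union of increased-activity intervals inside the epoch, and
   phasic activity within that epoch is re-detected against the elevated
   baseline, so only bursts at twice the tonic background survive.
7. **(Mini-)epoch scoring.** Each 30-s epoch splits into ten 3-s
   mini-epochs. A valid mini-epoch is *phasic* if it overlaps an event of
   up to 5 s and carries *any* activity if it overlaps an event of up to
   15 s or lies in a tonic epoch. Validity requires the (mini-)epoch to
   be free of any masked sample.
8. **Summaries.** Per channel: tonic/phasic/any counts and percentages of
   the artefact-free REM (mini-)epochs, plus arithmetic means of maximum
   amplitude and duration over phasic bouts and over phasic+intermediate
   ("any") bouts. Combined channels (by default mentalis-any + bilateral
   FDS-any, and mentalis-any + bilateral FDS-phasic) count a mini-epoch
   positive when any listed channel/category is positive, over the
   mini-epochs valid in *all* listed channels.

## A worked example

```{r example}
hyp <- Hypnogram(seq(30, by = 30, length.out = 20), rep("REM", 20))
bursts <- layoutBursts(hyp, "mentalis", nPhasic = 4, nIntermediate = 2,
                       nTonic = 1)
fx <- generateFixture(
  fixtureSpec(seed = 7,
              stages = data.frame(stage = c("W", "REM"),
                                  duration = c(30, 600)),
              bursts = bursts),
  tempdir())
rec <- readRecording(fx$paths[["edf"]])
hypB <- parseSleepProfile(fx$paths[["hypnogram"]], startTime(rec))
ev <- list(parseEvents(fx$paths[["arousal"]], "arousal", startTime(rec)))
scoring <- scoreRecording(rec, hypB, ev)
scoring
channelSummary(scoring)
verifyAgainstTruth(scoring, fx)
```

## Design decisions

Several points are underdetermined by the verbal rules; the package
resolves them as follows, and each is configurable where noted.

* **Grid and boundaries.** Event timestamps live on the 15 ms RMS grid.
  The activity threshold is strict (`>` 2x baseline: a window at exactly
  twice the baseline is not activity), the tonic rule is inclusive
  (`>=` 15.0 s), events split at interruptions of `>=` 0.25 s, and the
  phasic/intermediate boundary assigns a duration of exactly 5.0 s to
  phasic and anything in (5.0, 15.0] to intermediate (durations are
  continuous, so the nominal 5.0/5.1 gap is closed upward).
* **Epoch validity.** A (mini-)epoch is excluded from scoring and from
  denominators when *any* part of it is masked — the conservative
  reading of counting only artefact-free (mini-)epochs.
* **Detachment window.** The 0.05 mV detachment criterion carries no
  stated window; the package evaluates it with the 30 s baseline window
  (clamped to short segments), matching the baseline machinery and the
  "sustained silence" intent.
* **"Containing" a bout.** Mini-epoch flags use interval overlap, so an
  event crossing a mini-epoch boundary marks both mini-epochs;
  containment-only would make scoring depend on arbitrary grid
  alignment.
* **Tonic rescoring scope.** The tonic decision is made once per epoch
  from the original baseline; rescoring replaces only that epoch's
  phasic/intermediate events and never feeds back into the tonic flag
  (no fixed-point iteration), and neighbouring epochs keep the segment
  baseline. The elevated baseline is the RMS over the union of
  increased-activity intervals inside the epoch — the very intervals
  that made it tonic.
* **Events above 15 s outside tonic epochs** count toward neither phasic
  nor any activity: the "any" rule caps at 15 s, and an epoch whose long
  event did not reach 50% coverage is simply not tonic. This literal
  reading is deliberate.
* **Combined-channel denominator.** The intersection of the constituent
  channels' valid mini-epochs, the only choice under which every counted
  mini-epoch is assessable on every channel.
* **Baseline tie-breaks.** Nearest period by midpoint distance; exact
  ties to the earlier period; inheritance chains resolve transitively,
  previous-first.
* **Artefact policies.** Two first-class modes: `"full"` (arousal +
  respiratory + snore-on-mentalis) and `"arousal-only"`. Electrode
  detachment is excluded under both, since a detached electrode carries
  no physiological signal under either policy.
* **Filtering.** The 10–100 Hz band-pass and 50 Hz notch are zero-phase
  (forward–backward Butterworth) so burst onsets are not shifted, and
  opt-in: the default pipeline assumes recordings filtered at
  acquisition, as is standard for clinical PSG exports.
* **Text dialects.** No vendor grammar is published for the hypnogram
  and event exports; the shipped default
  (`"HH:MM:SS,fff; STAGE"` / `"HH:MM:SS,fff-HH:MM:SS,fff; LABEL"`) is a
  best-effort reconstruction, and every element (separator, decimal
  mark, stage vocabulary, case-insensitive) is configuration via
  `profileDialect()`, not code.
* **Summary format.** Summaries are written as spreadsheet-compatible
  CSV tables with fixed column semantics.

## The synthetic-fixture generator

`generateFixture()` produces a complete, deterministic test recording:
band-limited (10–100 Hz) Gaussian background scaled to a per-channel
baseline RMS (default 0.1 mV, above the detachment criterion),
multiplicative bursts at a controlled amplitude ratio with 10 ms cosine
on/off ramps, a stage architecture written as a hypnogram file, labelled
artefact intervals written as event files, and the EDF itself — plus a
ground-truth table. `expectedScores()` derives the intended
tonic/phasic/any counts from burst geometry alone, and
`verifyAgainstTruth()` matches detected events to injected bursts and
reports per-category precision/recall and boundary errors.

What the generator deliberately does **not** emulate: physiological EMG
spectra and motor-unit structure, ECG crosstalk, respiration and movement
waveforms (artefacts are injected as labelled intervals, not as
waveforms), inter-channel correlation, and non-stationary background
tone. Passing the recovery suite therefore demonstrates that the rules
are implemented correctly on signals with the assumed statistical
structure, not that the scorer is robust to every artefact of real
recordings.

Two statistical properties of the method itself surface in validation and
are worth knowing:

* **Detectability boundary.** Near the minimum event duration, detection
  is probabilistic: a 0.2 s burst spans only ~13 RMS cells, and the seed
  rule demands a *continuous* supra-threshold run of more than 0.1 s, so
  a single noise dip can split it. On the generator's background,
  0.2 s bursts at 3x baseline are missed roughly a quarter of the time,
  at 3.5x about 8%, and essentially never at 5x. The layout helper
  `layoutBursts()` therefore injects bursts at 5x baseline by default;
  equivalently, real bursts near 100 ms and near the 2x threshold are
  not reliably scored — visual scorers face the same ambiguity.
* **Boundary-extension tail.** A single 30 ms background window exceeds
  twice the baseline with probability ~1e-3 per 15 ms step. When such a
  stray window falls within 0.25 s of a true event edge, the
  gap-extension rule absorbs it, shifting the reported boundary by up to
  0.25 s. Event *counts* are unaffected (an isolated stray is far too
  short to seed an event, and the recovery fixtures keep 0.35 s margins
  to mini-epoch boundaries), but per-event boundary errors have a small
  heavy tail; typical onset errors stay within one window (30 ms).

## Problem sizes used in validation

The shipped test-suite checks run at desk scale: oracle-equivalence on
1000 randomized 2–6 s signals against a literal re-implementation of the
verbal rules; ground-truth recovery on fixtures of 5–26 REM epochs with
0, 3 and 8 bursts per category; and property checks (scale invariance,
mask monotonicity, phasic-within-any containment, determinism,
round-trips) on 10–20-minute recordings. `scripts/acceptance.R`
regenerates the same quantities from scratch for any seed.

## Limitations

* No automatic artefact classification beyond the detachment rule: the
  scorer trusts the provided arousal/respiratory/snore annotations.
* The hypnogram is an input; no sleep staging is performed.
* Chin tonic estimates inherit the high intrinsic ambiguity of tonic
  scoring; combined chin+FDS metrics are the more robust readout.
* Diagnostic cut-offs are study results, not tool behaviour: the package
  reports percentages and leaves classification to the user.
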