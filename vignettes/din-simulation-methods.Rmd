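---
title: "Simulated digits-in-noise testing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated digits-in-noise testing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dintest)
library(dplyr)
```

## The measurement problem

A digits-in-noise (DIN) test estimates how well a person understands speech
in background noise. Each trial presents three random, non-repeating spoken
digits mixed with a masker at some signal-to-noise ratio (SNR, the speech
level minus the noise level in dB); the listener repeats them, and the
response is correct only if all three digits come back in the presented
order. An adaptive staircase then steers the SNR toward the listener's
speech reception threshold (SRT): the SNR at which they achieve a criterion
proportion of correct triplets. Negative SRTs are the norm — speech remains
intelligible below the long-term level of the masker.

`dintest` implements the full test engine — staircase, stimulus assembly at
exact SNR, response normalization and scoring, session orchestration — plus
a *virtual participant layer*, so the whole design of a three-variant DIN
study (a spoken-response test scored by a speech recognizer, a keyboard
twin of it, and an independently implemented reference test) can be run and
evaluated in silico, with no audio hardware, recognizer models or human
subjects.

## The adaptive staircase

All three variants use a transformed up-down (2-down/1-up) rule: after two
consecutive correct triplets the SNR is lowered (harder) by the current
step; after any incorrect response it is raised. This rule converges near
the 70.7%-correct point of the per-trial psychometric function. The
consecutive-correct counter resets after every SNR decrease and after any
incorrect response.

A *reversal* is a change in the direction of the SNR track. Step sizes are
scheduled by reversals completed:

| preset | steps (dB) | reversal budgets | start SNR | level policy |
|---|---|---|---|---|
| `ai_powered`  | 5 / 3 / 1 | 2 / 2 / 6 | +5 dB | digits fixed at 65 dB SPL, noise adaptive, capped at 80 dB SPL |
| `keyboard`    | 5 / 3 / 1 | 2 / 2 / 6 | +5 dB | identical to `ai_powered` |
| `independent` | 6 / 2     | 4 / 6     | +2 dB | overall digits-plus-noise RMS held at 65 dB SPL |

A run ends at the tenth reversal, and the SRT is the mean SNR of the
final-phase trials. With digits fixed at 65 dB SPL, the 80 dB SPL noise cap
implies an SNR floor of −15 dB; a listener who keeps answering correctly
there has their result recorded as "−15 dB or lower" after six correct
responses at the floor.

Several bookkeeping details are genuinely underdetermined by that
description, and the package fixes them as follows:

* **Reversal definition.** Direction is undefined until the first actual
  SNR movement; a reversal is counted when a movement's sign differs from
  the previous movement's sign. This is the standard staircase convention.
* **Step scheduling.** The step for a movement is the one belonging to the
  phase containing the reversals completed *before* that movement, so a
  phase advance takes effect on the next movement.
* **SRT estimator.** "Averaging the final-phase SNRs" is read as the mean
  over every *trial* presented during the final phase (including the trial
  that produces the tenth reversal). Averaging only the final-phase
  reversal points is available behind
  `srt_estimator = "mean_final_phase_reversal_snrs"`. The independent
  variant applies the same rule to its final (second) phase.
* **Floor counting.** The six correct-at-floor responses are counted
  cumulatively within a run, not necessarily consecutively — the
  conservative reading, since the rule exists to terminate unmeasurable
  runs early.
* **Clamping.** A movement that would cross the floor is clamped to it but
  keeps its direction for reversal bookkeeping, preserving the monotone
  semantics of the track at its bounds.
* **The independent preset has no floor.** Its source description states
  none; consequently an impossibly good responder produces a runaway
  session, which `run_session()` converts into an error at a 200-trial
  safety cap rather than a fabricated result.

`replay_track()` re-applies a logged correctness sequence through the
update rule; by construction any archived session must reproduce its SNR
trajectory exactly, and the test suite asserts this for every simulated
session it touches.

## Stimulus assembly and level calibration

Physical calibration is replaced by a software `calibration_map()`: one
constant assigning a dB SPL value to a digital RMS of 1.0 (default 100 dB,
so 65 dB SPL is a digital RMS of 10^(−35/20), leaving ample headroom). All
level arithmetic is pure 20·log10 gain.

`assemble_stimulus()` lays out one trial: the three digit waveforms with a
configurable inter-digit gap, noise starting 0.5 s before the first digit
and ending 0.5 s after the last, sample-accurately. Two conventions are
config-exposed because no single convention is canonical:

* **Inter-digit gap** defaults to 0.5 s, a typical DIN pacing.
* **SNR measurement window.** Speech level is the RMS of the digit content
  (gaps excluded); the noise gain is computed from the masker's RMS
  *measured over the speech span*, not over the whole excerpt. With this
  definition the requested and realized pre-mix SNR agree to machine
  precision for any masker excerpt, and the lead/trail padding cannot
  dilute the measurement.

Under the constant-overall-level policy the assembled mixture is rescaled
so that the overall stimulus RMS equals the configured 65 dB SPL at every
SNR — the audibility-preserving scheme of the independent variant — making
the overall level exactly constant across a session.

The synthetic fixtures (`make_din_fixtures()`) are harmonic complexes with
digit-specific fundamentals (0.3–0.8 s) and a stationary speech-shaped
noise (Gaussian noise through a one-pole lowpass). They reproduce the
*shape* of a DIN stimulus inventory — ten short utterances, a five-minute
masker at 22.05 kHz — for level, timing and pipeline testing. They are not
intelligible speech, so nothing about human digit recognition should be
inferred from them; they exist so that every level and timing contract can
be tested end-to-end in a text-only, seed-reproducible repository.

## Response scoring

Spoken transcripts from a general-purpose recognizer arrive as free text
("six one, too"). `normalize_transcript()` lower-cases, strips punctuation
and resolves each token through a homophone dictionary
(`word<TAB>digit` per line; the shipped file is a curated confusion list
and can be replaced wholesale). Unresolvable tokens are data, not errors.
`score_response()` is deliberately strict: exactly three resolved digits,
equal position-by-position to the presented triplet; permuted, short,
over-long and empty responses all score incorrect. The keyed and spoken
paths therefore produce identical scores for equivalent content, which the
suite checks property-style.

## The virtual participant

The listener is a logistic psychometric function over triplet correctness:

p(SNR) = guess + (1 − guess − lapse) · logistic(4 · slope · (SNR − threshold))

parameterized so `slope_per_db` is the derivative at threshold and
p(threshold) sits midway between the asymptotes. Defaults — slope 0.15/dB,
lapse 0.01, guess 1/720 (one of the 720 ordered triplets) — are fixture
choices of plausible magnitude for a triplet task, not empirical claims.
A per-digit mode (triplet probability = per-digit probability cubed) is
available; the staircase itself only ever consumes triplet correctness.

The recognizer is modelled at the response level by a single corruption
probability: a correctly spoken triplet is, with that probability,
transcribed with one uniformly chosen digit substituted. Corruption never
repairs a wrong answer — the model is asymmetric by design, matching how
mis-transcriptions are tallied: a trial wrong through both the listener
and the recognizer counts against the listener, because the staircase
would have moved the same way regardless.

Randomness is split into per-run substreams (triplet, listener,
recognizer) derived from one root seed. This matters beyond replayability:
when sweeping the corruption level, the listener's draws are shared across
levels, so the degradation of test–retest agreement is measured against a
paired baseline instead of fresh sampling noise.

## The simulated study and its evaluation

`experiment_plan()` describes the whole design: 21 normal-hearing and 10
hearing-impaired virtual participants by default, each performing three
spoken-response runs, two independent-test runs and one keyboard run in a
fixed order. Group SRT-threshold ranges default to −12…−8 dB
(normal-hearing) and −7…0 dB (impaired) — values in the range DIN tests
report for such groups, chosen once as generator conditions.

`analyze_experiment()` reproduces the evaluation grid of a three-test
agreement study: validity (spoken vs independent), its keyboard baseline,
and test–retest reliability of the spoken and independent tests, each with
and without outlier exclusion. The recognizer error rate of a run is the
percentage of its incorrect trials caused by mis-transcription; exclusion
uses the mean rate over the spoken runs (validity) or the worse of runs 1
and 2 (reliability), with a 40% default threshold. Agreement is summarized
by Bland–Altman bias and 95% limits of agreement (bias ± 1.96·SD of the
paired differences; no small-sample correction), Pearson correlation and
RMSE. Floored SRTs enter at the floor value but are flagged as bounds.

```{r example}
ex <- run_experiment(experiment_plan(n_normal = 8, n_impaired = 4,
                                     corruption_prob = 0.1, root_seed = 7))
analyze_experiment(ex) |>
  select(comparison, exclusion, n, bias, loa_halfwidth, pearson_r, rmse)
```

## Numerical choices and problem sizes

* SRT and level arithmetic is double precision throughout; the only
  tolerance constants are in tests (0.1 dB for realized SNR, 1e−9 for
  agreement statistics against first-principles recomputation).
* The convergence property is checked over 200 seeded runs against a
  logistic listener, asserting the mean SRT lies within 1 dB of the
  listener's 70.7%-correct SNR; the same-size paired designs (200 virtual
  participants) back the null-difference and corruption-degradation
  properties. These sizes put Monte-Carlo error well inside the asserted
  margins while keeping the whole suite fast to run routinely.
* Test fixtures use a 30 s masker rather than the full 5-minute one; the
  masker is stationary by construction, so its length only needs to cover
  the longest assembled stimulus with room for offset sampling.

## What passing simulations do and do not show

The virtual listener honours the staircase's own assumptions: a stationary,
memoryless psychometric function with no fatigue, learning, lapses in
attention beyond the constant lapse rate, or trial-to-trial correlation —
and the recognizer model is a single corruption probability, not an
acoustic system. Green simulation properties therefore validate the *test
mechanics and analysis pipeline* (stepping, bookkeeping, scoring, levels,
statistics), and the qualitative behaviour of the design under recognizer
degradation. They cannot certify how a recognizer behaves on real speech,
nor reproduce agreement statistics measured on human participants, which
depend on listener populations and recording conditions outside the model.

## Extending to real operation

The engine never touches audio models directly: a synthesizer is any
function from a digit string to an `audio_buffer`, and a recognizer any
function from an `audio_buffer` to transcript text. Attaching pretrained
text-to-speech and speech-recognition systems is a matter of implementing
those two contracts and replacing the virtual participant with a capture
loop; the staircase, scoring and analysis layers are unchanged.
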