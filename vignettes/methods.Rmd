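---
title: "Detecting and modelling anticipatory gaze switches at turn transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and modelling anticipatory gaze switches at turn transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turngaze)
```

## The measurement problem

Listeners project upcoming conversational structure: before a speaker has
finished, an attentive observer often shifts gaze to the person who is about
to respond. In screen-based studies of this behaviour, toddlers and adults
watch videos of two puppets holding short scripted conversations while an eye
tracker records where they look. The analytic question is whether, at
engineered potential turn ends, observers shift their gaze to the upcoming
responder *before* they could have merely reacted to the response itself —
and whether the rate of such anticipatory switches depends on the linguistic
cues available at the potential turn end.

turngaze implements this measurement chain end to end: the stimulus design,
the sample-level preprocessing, the switch detector, a Monte Carlo chance
baseline, and the mixed-model analysis, together with a synthetic gaze
generator so every stage can be exercised and validated without any
participant data.

## Stimulus design

Each experiment consists of eight conversations of about 30 s between a LEFT
and a RIGHT puppet. A conversation has ten utterances — six fillers and four
targets — separated by exactly 500 ms of silence. Each target is engineered
in one of four completeness conditions crossing lexicosyntax and prosody:

```{r}
condition_table()
```

At the onset of the target's 500 ms silence, the utterance so far is either a
complete polar interrogative (+SYN) or an unfinished declarative (−SYN), and
either carries a question-final rise (+PROS) or lacks any boundary contour
(−PROS). Syntactically incomplete targets are always followed by a
continuation of the same speaker (an unfinished utterance cannot cede the
turn); syntactically complete targets are followed by an actual speaker
change exactly half of the time, so that a speaker change is never fully
predictable from the cue structure alone.

`generate_design()` draws a design satisfying all published constraints:
one target per condition per conversation (32 targets in total, 8 per
condition), targets equally divided between the puppets (and, per condition,
4/4 between the two sides), five to seven speaker transitions per
conversation, and two counterbalanced presentation orders. Where the design
space is under-determined the generator makes the following conventions,
fixed once:

* **Filler durations.** Utterance durations are drawn uniformly from
  1.5–3.5 s and rescaled so the conversation length lands in 29.3–30.7 s;
  only the ~30 s total and the 500 ms gaps are prescribed.
* **Which +SYN targets switch.** The 4-of-8 speaker-change balance per
  condition is assigned by seeded permutation across conversations; only the
  overall 50% rate is prescribed, and it is enforced at the experiment
  level, not within conversations.
* **Target positions.** Targets occupy non-adjacent slots 2–9 of the
  ten-utterance sequence so each target is followed by an utterance whose
  speaker can encode the outcome.
* **Time base.** Integer milliseconds from conversation onset; all intervals
  half-open `[onset, offset)`, which makes every downstream rule
  sampling-rate independent.

`validate_design()` re-checks every constraint and returns a list of named
violations, so externally supplied design files (`load_design()`,
`save_design()`; YAML) are held to the same contract.

## Preprocessing and exclusion rules

Samples count as valid when the tracker marks at least one eye valid
(`is_valid_sample()`; the valid code set is dialect-configurable, default
codes 0 and 1). Valid samples are classified into `LEFT`, `RIGHT`, `OTHER`
(on screen, neither puppet) or `OFFSCREEN` by closed rectangular areas of
interest; the puppet AOI geometry is not part of the published record, so the
default layout (two large rectangles covering the screen halves, separated
by a small gap) is a package convention and fully configurable.

Exclusions follow two strict rules, both computed on the time axis:

* a trial is excluded when the on-screen fraction of its duration is
  **strictly below 75%** (a trial at exactly 75% is retained);
* a participant is excluded entirely when **more than four** trials were
  excluded (exactly four is retained).

Each sample's dwell is the interval to the next sample; the last sample gets
the median interval. Whether "attending to the screen" should count only
tracker-valid samples is not specified in the published record; turngaze
counts valid on-screen samples, which is the conservative reading (an
invalid sample cannot support an attention claim). Equipment-error drops are
an input-level list (`drop_participants`), recorded rather than recomputed.

## Switch detection

Fixations are maximal constant-AOI dwell runs; same-AOI runs separated by at
most `gap_tolerance_ms` (default 75 ms) of other material are merged, which
bridges single-sample tracker dropouts at 50 Hz (tracker recovery is faster
than 100 ms) without bridging genuine looks away. No minimum duration is
imposed at segmentation; the dwell criterion lives in the detector.

Each target's analysis window is centered on its 500 ms silence and extended
by the group *anticipation lead* on both sides: 300 ms for toddlers (the
minimum time a toddler needs to plan a gaze shift) and 200 ms for adults.
A switch is anticipatory when:

1. a fixation on the **prior speaker** of at least 100 ms overlaps the
   pre-silence part of the window;
2. sometime thereafter a fixation on the **responder** of at least 100 ms
   occurs; and
3. that responder fixation is **initiated** (fixation onset) no later than
   the lead after the response-turn onset, i.e. by `silence_offset + lead`.

Numerical conventions worth stating explicitly:

* The window extent `[silence − lead, silence + lead]` is the shortest
  window that honours the "centered on the silence" description while
  containing the criterion-3 deadline; windows are clipped at conversation
  bounds.
* "Initiated" is the onset of the responder-AOI fixation — AOI streams carry
  no saccade velocities.
* The response-turn onset is the silence offset for *both* speaker-change
  and continuation targets, since anticipation is being measured whether or
  not a response actually follows.
* Criterion 1's "at the end of the prior turn" is read as *overlap with the
  pre-silence window portion*; a stricter reading (the fixation must cover
  the final 100 ms of the turn) is available as `strict_prior = TRUE`.
* Criterion 2's fixation only needs to *start* by the deadline ("initiated");
  it may extend past the window.
* Half-open intervals fix all boundary cases: a fixation ending exactly at
  the silence onset does not overlap the silence; a fixation starting
  exactly at the deadline still counts as initiated in time.

The detector is validated against a brute-force enumeration of all
fixation pairs applying the three criteria literally, on thousands of
randomly generated fixation sequences, and obeys two monotonicity
properties: shrinking the window or raising the dwell criterion can never
create a detection.

## Chance baseline and corrected scores

Random back-and-forth looking can satisfy the three criteria by accident, so
each observed 0/1 indicator is corrected by an empirical chance rate: the
conversation's analysis windows are repositioned uniformly at random over
`[0, duration − window length]` 100 times (lengths, speaker roles and the
internal deadline geometry preserved), the detector is re-run against every
repositioned window, and the mean over the 100 replicates is that target's
baseline. The corrected score is `actual − baseline`, in `[−1, 1]`.

Conventions: shuffled windows may overlap each other and the real silences
(no exclusion zone is prescribed); each shuffled window copies its original
target's prior/responder roles; and placements are drawn **once per
conversation × group** and reused for every participant — matching the idea
of "100 shuffled versions of the original window placement" — with
`per_participant = TRUE` available since the published record does not state
which was done. The baseline is always empirical; no closed-form chance
model is used.

The key calibration property, verified in the test suite on a 40-participant
cohort with side-symmetric random gaze and zero anticipation: per-condition
grand means of corrected scores lie within three Monte Carlo standard errors
of zero.

## The model suite

Analyses are linear mixed-effects models (lme4, REML) on corrected scores
with crossed random intercepts for subject and item and all two-level
predictors contrast-coded −1/+1 (incomplete/complete, toddler/adult,
no/yes speaker change, incomplete-syntax/incomplete-prosody). A fixed effect
is significant when `|z| = |beta/SE| > 1.96`; no multiple-testing correction
is applied, and no p-values beyond this convention are computed. REML is the
package's choice — the published record names the significance convention
but not the estimator settings.

`run_model_suite()` fits, in order: the full factorial
`syntax × prosody × group` model on all targets; the partial-conditions
model (`condition × group` on the two mixed-cue conditions — the direct test
of cue weighting); the `prosody × group` model on syntactically complete
targets; the same subset adding the speaker-change contrast and its
interactions (a check that switches are not driven by the responding
puppet's movement); and refits of the main model on the first two and last
two conversations in presentation order (positions {1, 2} and {7, 8}) — a
check against statistical learning of the continuation bias over the
session. Items with ambiguous prosodic contours can be excluded via
`exclude_items`; the default fits all items.

Condition summaries report means ± SEM of actual, baseline and corrected
scores per condition × group; the SEM is computed over participant means
(between-participant variability), with a per-observation option.

Degenerate fits (e.g. a constant response) are flagged (`singular`,
`degenerate`) rather than raised: coefficients fall back to ordinary least
squares on the fixed part with zero random-effect variances.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` produces gaze tables with the exact schema the readers
expect, over a generated design, with known ground truth:

* **Background gaze.** By default a speaker-following process: gaze moves to
  each new speaker at utterance onset plus a reactive latency (toddler mean
  500 ms, SD 150, floor 350; adult mean 400, SD 100, floor 250). The floors
  are deliberately *above* the group anticipation deadline, so a purely
  reactive observer produces zero detections — anticipation in the
  simulation comes only from the anticipation mechanism. A side-symmetric
  alternating process (exponential dwells, mean 1 s) is available for null
  calibration.
* **Anticipation.** At each target, with a per-condition probability
  (defaults 0.10 / 0.25 / 0.50 / 0.70 in the order fully incomplete,
  incomplete syntax, incomplete prosody, fully complete — numeric
  conventions chosen to reproduce the qualitative cue-weighting ordering,
  not published values), a responder-directed shift is planned at the
  silence onset plus a planning latency (toddler mean 500 ms, SD 150, floor
  300 — the planning floor toddlers are known to need; adult mean 350, SD
  100, floor 150). Draws exceeding the criterion-3 deadline are kept: they
  become intended-but-late switches scored 0, preserving a realistic miss
  rate.
* **Noise.** Attention lapses (Poisson episodes, default 0.03/s, mean
  800 ms, half off screen) and per-sample validity dropout (toddler 5%,
  adult 1%). Coordinates are emitted with jitter clipped inside the AOI
  rectangles.
* **Ground truth.** Every gaze event is snapped to the sample grid, and each
  target's label is the detector criteria evaluated on the noise-free event
  timeline. With noise disabled, the sample-level pipeline must reproduce
  the labels exactly (the closed-loop test); with noise enabled, detection
  may miss intended switches, which is the realistic regime.

The generator does **not** model comprehension, linguistic content, pupil
dynamics, smooth pursuit, calibration drift, or any audiovisual rendering.
Passing tests on synthetic cohorts therefore demonstrate that the pipeline
measures what it defines — not that real toddlers behave like the generator.
In particular the per-condition effect sizes are conventions; only their
ordering and the null regime are meaningful test fixtures.

## Problem sizes and reproducibility

The package's own validation uses desk-scale cohorts chosen to keep the full
suite fast while leaving comfortable statistical margins: the null
calibration uses 20 + 20 participants with 100 shuffles; the effect-recovery
study uses 100 replicate cohorts of 10 + 10 participants; structural tests
use 2–8 participants. The acceptance script runs the study-sized cohort
(21 toddlers + 16 adults, 100 shuffles).

A single master seed fans out to named substreams (design, cohort,
shuffles), so each stage is independently reproducible and a rerun with the
same seed is byte-identical end to end. All seeded operations restore the
caller's RNG state.

## Known limitations

* The chance baseline is exchangeable over window placements only if the
  gaze process is stationary over the trial; strong drifts in attention
  (e.g. fatigue within a 30 s conversation) bias real and shuffled windows
  differently.
* The published trial accounting (total observation counts) does not close
  exactly against 32 targets × N participants; turngaze reports its own
  audit counts and asserts only design-determined quantities.
* With pre-resolved AOI streams the segmentation cannot distinguish a
  tracker dropout from a true look away; the gap tolerance treats both as
  bridgeable when short.
* `|z| > 1.96` is an asymptotic convention; for small cohorts the test
  suite relies on effect recovery rates rather than calibrated error rates.
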