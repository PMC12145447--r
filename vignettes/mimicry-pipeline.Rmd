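---
title: "Scoring positive emotional mimicry from dyadic AU time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring positive emotional mimicry from dyadic AU time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsmile)
```

## The measurement problem

Emotional mimicry — automatically joining a counterpart's emotional
expression — has four working features: the expressions match, they are
temporally aligned within seconds, the mimicker's expression is contingent
on the partner's, and the display is shared rather than merely reactive.
Whole-signal synchrony statistics (windowed cross-correlation of two
expression time series) blur these features together and are easily driven
by speech-related facial motion. `dyadsmile` instead detects *discrete
smile episodes* per participant and matches them across the dyad, so that
alignment and contingency are assessed event by event.

The input is the CSV output of an automated AU tracker (OpenFace 2.2
dialect) for two clips per participant: a short neutral *baseline* clip
(nominally 10 s) and the *interaction* clip (nominally 6 min), sampled at
30 Hz. Three action units carry the positive-expression signal: AU12 (lip
corner puller, zygomaticus major), AU06 (cheek raiser, orbicularis oculi),
and AU04 (brow furrow, corrugator supercilii).

## From AU intensities to a smile track

**Cleaning.** Frames where tracking failed (`success = 0`) or confidence
falls below 0.75 get their AU values linearly interpolated from the
nearest valid frames (dropping is available, but interpolation is the
default because all downstream arithmetic assumes an unbroken 30 Hz frame
grid). The tracker itself gives no guidance on how its failures were
handled in any particular study, so the cutoff is a documented default,
not a canon.

**Standardization.** Each interaction AU series is z-scored as
`(AU − mean(AU_baseline)) / sd(AU_interaction)`. Note the asymmetry: the
*location* comes from the baseline clip (neutral face = 0) while the
*scale* comes from the interaction clip itself. Dividing by the baseline
SD instead is a plausible alternative (the baseline clip is short and
near-constant, which would make the scale fragile); the interaction-SD
form is the default and the package treats it as the method's definition.
The SD convention is the sample SD (n − 1); a population-SD switch exists
because short series make the distinction visible.

A constant AU series (SD exactly 0) has no meaningful z-score; the package
raises a degenerate-signal error naming the AU, with an optional `epsilon`
fallback for batch robustness.

**Composite score.** `((zAU12 + zAU06)/2) − zAU04`. The score is symmetric
in AU06/AU12 by construction and is computed per frame *before* filtering;
the filter is applied once to the composite, not per AU (filtering is
linear, so the only difference would be bookkeeping).

**Filtering.** A second-order Butterworth low-pass, applied
forward–backward so the phase response is zero: a causal filter would
delay every onset by a substantial fraction of a second and bias the 2 s
matching window. The nominal cutoff value 0.05 is dimensionless in the
method's statement; the package reads it by default as a fraction of
Nyquist (0.05 × 15 Hz = 0.75 Hz at 30 Hz), which preserves the
multi-second structure of smiles. A literal 0.05 Hz reading (period 20 s)
would smear neighbouring smiles into plateaus and is available as
`cutoff_units = "hz"` for sensitivity analysis. The zero-phase pass is
implemented with steady-state initial conditions and odd-reflection
padding, so a constant signal passes through bit-exactly and edge
transients decay within tens of frames.

**Detection.** The threshold is `mean(score) + 1·sd(score)` over the
entire interaction recording. A smile is a maximal run of frames *strictly
above* the threshold, reported 1-based inclusive (first frame above, last
frame above). Two smiles separated by *strictly less than* 2 s are merged
into one (start of the first, end of the second), chained left to right;
a gap of exactly 2 s stays split. Manual verification is supported as an
edits overlay: removals (any overlapped interval is deleted) are applied
before additions, and an addition overlapping a retained interval is a
validation error rather than a silent merge.

## Shared smiles and the mimicry score

A smile is **shared** when at least one partner smile lies within the 2 s
window. The distance between two smiles is 0 when their intervals overlap
and otherwise the gap between the nearer endpoints; a distance of exactly
2 s *counts as shared* (within the window), deliberately contrasting with
the strict inequality of the merge rule — both boundaries are unit-tested.
An onset-to-onset latency predicate is available behind
`predicate = "onset_latency"` for sensitivity analysis, but the default
interval-gap reading is what reproduces the published worked example, in
which two smiles of one participant can share a single smile of the other
and the two partners legitimately have different shared counts.

The **mimicry score** of participant X is the number of the *partner's*
smiles that were shared divided by the partner's total: the fraction of
the partner's smiles X joined. When the partner never smiled, the score is
undefined and reported as `NA`, never 0 — no opportunity to mimic is not
evidence of no mimicry. The **smile ratio** is the fraction of interaction
frames inside smile intervals.

Frame conventions: intervals are 1-based inclusive everywhere in the API;
the gap between `[s1, e1]` and `[s2, e2]` is `s2 − e1 − 1` frames (frames
strictly between). At 30 Hz the merge rule therefore fires when the gap is
< 60 frames and the shared rule when it is ≤ 60.

## The synthetic dyad generator

Every stage is testable against ground truth through `simulate_dyad()`:

- **Events.** Spontaneous smile onsets per participant follow a Poisson
  process (default 3/min, matching smile counts in the high teens to
  twenties over six minutes); durations are lognormal (median 1.5 s,
  sigma 0.35). Each spontaneous smile of one participant triggers a
  partner mimic with probability `mimic_prob` after a uniform latency
  (default 0.3–1.5 s, inside the 2 s matching window). Triggering is
  one-step — mimics do not themselves trigger — which captures contingency
  without full self-excitation. Events that would overlap an earlier one
  are thinned with a warning.
- **Signals.** Each smile adds a plateau bump with raised-cosine
  onset/offset ramps (0.2 s) to AU06/AU12 (amplitudes 1.8/2.2 on the
  tracker's 0–5 scale) and suppresses AU04; all channels get AR(1) noise
  (coefficient 0.9, innovation SD 0.05 — facial intensity estimates are
  temporally autocorrelated, and white noise would understate detection
  difficulty). Baselines are resting levels plus noise.
- **Study design.** `simulate_study()` emulates the repeated-measures
  layout: each interacting partner (IP) appears in exactly two dyads, once
  with a matched control (MAT) and once with an SCZ-labelled participant
  (the IP is then relabelled IPS). Group-effect multipliers scale rate,
  duration, and mimic probability per label; `power_matched_effects()`
  plants a large deficit (rate and mimic probability × 0.6 for SCZ),
  comparable to the standardized effect sizes reported for blunted
  positive expression.

What the generator does *not* emulate: speech-related zygomaticus
activity, tracker dropouts correlated with head pose, asymmetric or
non-Duchenne smiles, and drift in the baseline. Passing recovery tests
therefore validates the pipeline's arithmetic and its detector under
plausible noise — not the tracker itself, nor the human verification step.

## Recovery properties and problem sizes

Three recovery facts anchor the test suite, at sizes chosen to keep the
whole suite in the minutes range:

- **Detection.** On noiseless dyads the detected boundaries match ground
  truth to ≤ 2 frames (the residual displacement of threshold crossings on
  filtered ramps); because a 2-frame edge shift also shifts measured gaps
  by up to 4 frames, truth gaps that close to the 60-frame merge boundary
  may merge either way, and the comparison accounts for exactly that
  slack. With default AR(1) noise, mean detected counts stay within ±10%
  of truth over 50 simulated dyads.
- **Mimicry.** The mimicry score estimates `mimic_prob` only in a
  one-directional design (`mimic_recovery_config()`): a storyteller who
  never mimics faces a pure responder with no spontaneous smiles. Under
  symmetric mimicry the estimand is structurally larger than `mimic_prob`,
  because mimic smiles enter both the shared and the total counts — with
  `mimic_prob = 0.8` the symmetric estimand is ≈ 0.89, which is a property
  of the score's definition, not a bug. In the one-directional design with
  50 dyads the pipeline recovers 0.8 within ±0.05 (chance proximity
  contributes ≈ +0.02; spurious detections in sparse signals contribute a
  comparable negative term).
- **Group statistics.** With the power-matched SCZ deficit and 20 dyads
  per condition, the Tukey-adjusted MAT–SCZ contrast on smile counts is
  significant in ≥ 80% of 100 replicates; under null multipliers the
  familywise error over the three pairwise contrasts stays at or below
  0.05 plus Monte-Carlo tolerance (400 replicates). These calibrations run
  in the event-level simulator mode, which feeds the true (merged) smile
  intervals to the real matching, scoring, and model-fitting code while
  skipping AU-trace synthesis; signal-level fidelity is covered separately
  by the detection and mimicry recovery checks, and this split keeps a
  500-replicate calibration tractable on one core.

## Statistical modelling choices

`fit_group_model()` fits `outcome ~ group + (1 | id)` via lme4/lmerTest
with Satterthwaite degrees of freedom (chosen over Kenward–Roger for speed
and determinism in Monte-Carlo loops) and extracts all pairwise contrasts
with Tukey-family adjustment through emmeans. The grouping variable for
the random intercept is a parameter: participant id is the natural choice
for individual-level outcomes, dyad id for dyad-level ones. When the
random-intercept variance collapses to zero (common when only the IP rows
repeat), the fit falls back to OLS with a logged message — estimates are
then identical to the mixed fit, and the contrast machinery is unchanged.

Cohen's d for a mixed-model contrast has no single convention; the package
divides the contrast estimate by the pooled within-group SD of the raw
outcome — simple, reproducible, and stated here so readers know exactly
what was standardized. Degenerate inputs (zero residual variance with zero
estimates) report p = 1 and d = 0 rather than 0/0.

`symptom_correlations()` reports Pearson r and p for the outcome against
five clinical covariates with both the unadjusted decision at α = 0.05 and
the Bonferroni decision at 0.05/5 = 0.01, because reporting only one of
the two invites the classic ambiguity of "significant before correction".
`willingness_scores()` validates nine 1–5 items and sums them (range
9–45).

## Known limitations

- The mean+1SD threshold adapts to each recording; in very sparse, noisy
  recordings it sits low and admits noise excursions as false smiles. Real
  deployments keep the human verification step for exactly this reason.
- The worked-example counts (16/18 and 20/27) are reproduced from
  constructed interval geometry; the original recordings are not
  available, so published β, p, and d values for the group contrasts are
  not desk-reproducible and are covered by direction/power properties
  instead.
- Only the positive-expression composite is implemented; negative-emotion
  mimicry would need different AU sets and its own validation.
- Interval arithmetic is 1-based inclusive throughout; users porting
  half-open conventions should mind the `s2 − e1 − 1` gap definition.
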