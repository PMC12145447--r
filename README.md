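# dyadsmile

Quantify **positive emotional mimicry** in face-to-face dyadic interactions
from automated facial action-unit (AU) recordings.

When two people converse, they tend to mirror each other's smiles within a
few seconds. Blunted mimicry is of particular clinical interest in
schizophrenia research, where reduced facial expressivity degrades social
interaction quality. `dyadsmile` implements an event-based alternative to
whole-signal synchrony measures: it detects discrete smile episodes in each
participant, matches them across the dyad within a temporal window, and
scores mimicry as the proportion of the partner's smiles that were joined.
The package is aimed at researchers who record dyads on video, run an
automated AU tracker (OpenFace 2.2 CSV output), and want participant-level
mimicry outcomes plus group-level statistics.

## Method

For each participant the pipeline computes, at 30 Hz:

1. **Within-subject standardization.** Each AU intensity series from the
   interaction clip is baseline-corrected against a short neutral clip:
   `zAU = (AU_interaction − mean(AU_baseline)) / sd(AU_interaction)`, so 0
   means "no change from this person's neutral face".
2. **Composite positive-expression score.**
   `score = (zAU12 + zAU06)/2 − zAU04` — lip corner puller and cheek raiser
   up, brow furrow down — capturing smile valence with eye involvement.
3. **Smoothing.** A second-order zero-phase Butterworth low-pass filter
   (cutoff 0.05, interpreted by default as a fraction of Nyquist = 0.75 Hz
   at 30 Hz).
4. **Smile detection.** A smile is a maximal run of frames with score
   strictly above the participant's `mean + 1 SD` over the whole recording;
   runs separated by less than 2 s are merged; manual-edit files from human
   verification can remove or add episodes.
5. **Shared smiles and mimicry.** A smile is *shared* when a partner smile
   lies within 2 s (interval gap; overlap counts). The mimicry score of
   participant X is `(# partner smiles shared) / (# partner smiles)` — e.g.
   16 of 18 partner smiles joined gives 16/18 = 0.89, 20 of 27 gives 0.74.
   The *smile ratio* is the fraction of the interaction spent smiling.
6. **Group statistics.** Linear mixed models (`outcome ~ group +
   (1 | participant)`) with Tukey-adjusted pairwise contrasts and Cohen's
   d; willingness-to-interact totals (nine 1–5 items, range 9–45); Pearson
   correlations with symptom/medication covariates at a Bonferroni-adjusted
   threshold.

A fully parameterized **synthetic dyad simulator** (Poisson smile onsets,
partner-triggered mimic events with latency, raised-cosine AU bumps, AR(1)
noise, group-effect multipliers) provides ground truth for every stage.

## Worked example

```r
library(dyadsmile)

dir <- tempfile()
sim <- simulate_dyad(dyad_sim_config(mimic_prob = 0.7), seed = 42)
manifest <- write_dyad_clips(sim, dir)   # tracker-dialect CSVs + manifest
analyze_dyad(manifest)
#> # A tibble: 2 × 7
#>   dyad_id participant_id n_smiles n_shared smile_ratio mimicry_score group
#>   <chr>   <chr>             <int>    <int>       <dbl>         <dbl> <chr>
#> 1 dyad1   dyad1_IP_a           22       18       0.122         0.818 IP
#> 2 dyad1   dyad1_MAT_b          22       18       0.115         0.818 MAT
```

Each participant smiled 22 times, 18 of those within 2 s of a partner
smile; each spent ~12% of the six minutes smiling, and each joined
18/22 = 0.818 of the partner's smiles.

A simulated study with a planted smiling/mimicry deficit in the SCZ group
(20 dyads per condition, interacting partners relabeled IPS when paired
with SCZ):

```r
st  <- simulate_study(20, dyad_sim_config(group_effects = power_matched_effects()),
                      seed = 1, mode = "events")
fit <- fit_group_model(st$outcomes, "n_smiles")
fit
#> Group comparison of 'n_smiles' (OLS fallback, singular random intercept)
#> Group means:
#>  group  n mean   sd
#>     IP 20 20.2 3.07
#>    IPS 20 18.2 3.99
#>    MAT 20 20.6 3.83
#>    SCZ 20 13.3 2.36
#> Tukey-adjusted pairwise contrasts:
#>   contrast estimate   se df conf_low conf_high p_adjusted cohens_d
#>   IP - IPS     2.00 1.07 76   -0.806     4.806   2.49e-01    0.592
#>   ...
#>  MAT - SCZ     7.35 1.07 76    4.544    10.156   8.70e-09    2.176
```

The planted deficit surfaces exactly where expected: SCZ differs from every
other group (e.g. MAT − SCZ = 7.35 smiles, d = 2.18) while IP, IPS and MAT
are mutually indistinguishable. `tidy(fit)` and `glance(fit)` return the
contrast and model summaries as tibbles; `autoplot(fit)` draws the
contrasts, and `plot_expression_signal()` / `plot_shared_smiles()` display
the per-participant signals and matched smiles.

## Repository layout

- `R/` — implementation: tracker I/O, scoring, smile detection, dyad
  matching, simulator, group statistics, plotting, command wrappers.
- `inst/cli/dyadsmile.R` — thin shell entry point
  (`score | detect | dyad | simulate | stats`).
- `tests/testthat/` — unit, property (brute-force oracle), and end-to-end
  recovery tests.
- `vignettes/mimicry-pipeline.Rmd` — the methods vignette: model,
  parameter choices, simulator design, numerical decisions, limitations.
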