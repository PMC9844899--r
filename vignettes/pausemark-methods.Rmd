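---
title: "Detecting minimal-response rupture markers from speech pauses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting minimal-response rupture markers from speech pauses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Alliance ruptures — moments in which the collaboration between a patient and
their psychotherapist deteriorates — are coded by trained observers watching
session recordings, a procedure too expensive to scale to whole treatments.
Withdrawal-type ruptures in particular are easy to miss: the patient goes
quiet rather than confrontational.  The *minimal response* marker (the
patient answers discussion-initiating statements minimally or not at all)
has an acoustic shadow that needs no transcript: speech pauses, and
especially pauses that are both preceded and followed by therapist speech
(the therapist carries the dialogue alone, the patient skips their turns).

`pausemark` implements an audio-only pipeline for this setting:

1. **Silence detection** on the single boundary-microphone channel, by
   amplitude-range histograms with a data-driven cut-off.
2. **Supervised speaker diarisation** of the detected speech into patient
   and therapist turns from a small labelled learning set.
3. **Speaker-switching patterns**: each pause is labelled `P_P`, `P_T`,
   `T_P` or `T_T` by the speakers of the adjacent utterances.
4. **Windowing**: 10-second windows carrying total and per-pattern pause
   percentages, joined with the observer's rupture annotations.
5. **Mixed-effects analyses** of the pause-rupture association and a
   **random-forest classifier** of minimal-response windows from lagged
   pattern-pause features.

Because the clinical recordings on which the method was developed cannot be
redistributed, the package also ships a calibrated **synthetic session
generator**.  The generator is first-class, tested code: it plants the
statistical structure that the pipeline is supposed to recover, and the
test suite and the acceptance script measure that recovery.

## Silence detection

Speech yields a variable signal; its absence leaves only the recording
chain's noise floor.  `compute_range_series()` takes the max-minus-min
amplitude range in non-overlapping 0.01-s windows; over a session the
distribution of these ranges is strongly right-skewed, with silent windows
piled into a narrow peak at the left.  `calibrate_cutoff()` bins the ranges
with Scott's rule (`3.49 * sd * n^(-1/3)`) and places the cut-off at the
upper edge of a selected bin.  Where the original workflow selected the bin
by listening probes, the default `valley` strategy automates the choice for
reproducibility: after a 3-bin moving-average smoothing (robustness against
sparse bins; configurable), the leftmost bin at which the descent from the
silence peak stops is taken.  The manual `index:k` strategy is preserved
for parity with ear-calibrated work.  `classify_silence()` then applies the
cut-off to 0.1-s windows, and `merge_to_episodes()` turns maximal silent
runs into pause episodes on the 0.1-s grid.

Numerical choices worth knowing:

* The final partial window of a series is dropped.
* Pause timestamps are quantised to the 0.1-s evaluation grid, so a
  detected episode can be up to ~0.2 s shorter than the true pause; with
  conversational gaps of ~1.8 s this bounds the achievable time-weighted
  IoU near 0.92–0.95, which is what the recovery tests observe.
* `apply_min_duration_filter()` implements the "silence" convention used in
  psychotherapy research (keep pauses of at least 3 s); the comparison is
  inclusive at exactly 3.0 s.
* A zero-variance range series means no speech was recorded and is an
  error, not an all-silent classification.

## Diarisation

`extract_features()` describes each non-overlapping 0.2-s window with 35
features: 13 MFCC means and 13 MFCC standard deviations (aggregated over
25-ms/10-ms sub-frames), mean fundamental frequency (spectral peak in the
60–400 Hz band), energy, zero-crossing rate, spectral centroid, rolloff,
flux, flatness, bandwidth and harmonic ratio.  Feature inventories of this
kind differ between toolchains and the original library's exact list is not
recoverable; the set here is fixed, documented, and treated as the
package's default rather than a reconstruction.  Unvoiced windows carry an
F0 of 0 with no extra indicator column, keeping the column count at 35.

`train_diariser()` fits a random forest (500 trees by default; a seed is
mandatory) on the windows inside the labelled learning-set segments — the
workflow expects at least five labelled minutes per speaker, enforced as a
warning by default so small fixtures remain usable, and as an error with
`strict = TRUE`.  `segment_turns()` attributes each maximal inter-pause
speech run by majority vote over its window labels; ties go to the previous
turn's speaker, and the session opener defaults to the therapist, who
conventionally invites the patient to start.  Utterance-level attribution
(rather than per-window smoothing) is used because the downstream pattern
definitions are stated in terms of utterances.

## Patterns, windows, features

`label_patterns()` assigns each pause the speakers of its nearest
neighbouring turns.  Pauses at the session edge have no neighbour on one
side; they get an explicit `BOUNDARY` label and are excluded from the four
pattern features rather than being given a fabricated neighbour.

`window_session()` cuts the session into 10-s windows (trailing partial
window dropped) and apportions every pause to windows *exactly* by overlap,
so pause seconds are conserved to grid resolution — a property asserted in
the tests.  A window counts as rupture when episodes cover at least half of
it (threshold configurable; exact halves count as rupture), and inherits
the covering episode's dominant type, marker and id.

`zscore_by_dyad()` standardises the four pattern percentages per dyad over
*all* of that dyad's windows, before any subsetting.  The alternative order
(subset to ruptures, then standardise) produces different features; the
package fixes and documents scale-first, which keeps the features
comparable between rupture and non-rupture windows at evaluation time.
`add_lags()` shifts the four standardised columns by −5…+5 windows within
session (4 × 11 = 44 features); offsets that would cross a session edge are
imputed with 0 — the per-dyad mean on the z-scale — and counted in a QC
attribute, preserving short ruptures near the edges instead of dropping
their rows.

## The marker classifier

Rupture windows only are used for training (non-rupture windows would
swamp the ~3%-prevalence marker class).  `split_ruptures()` allocates whole
episodes — never windows — to training or validation, stratified by dyad
and marker status; within a stratum, shuffled episodes fill the training
side until it holds closest to 2/3 of the stratum's rupture *seconds*, a
length-weighted reading of the sampling design.  Strata with one episode go
to training with a warning.  `train_rupture_classifier()` is a 500-tree
random forest with 6 variables tried per split, out-of-the-box otherwise;
it reports the out-of-bag error and permutation (mean-decrease-accuracy)
importances.  `evaluate_classifier()` scores validation windows by vote
fraction, sweeps every threshold for the ROC, and reports the rank-based
AUC (ties get half credit) — the two AUC constructions agree to numerical
precision and are cross-checked against an independent implementation in
the tests.  Both evaluation variants are reported: rupture windows only,
and with all non-rupture windows added as negatives (by definition they
contain no minimal-response marker).  No decision threshold is calibrated;
the method is a proof of principle and the AUC is the endpoint.

## Mixed models and time course

Both models use percent of pauses per 10-s window as the response and a
random intercept by dyad, fitted by REML; p-values use Satterthwaite-style
degrees of freedom (the standard choice where the original tooling is not
specific).  Model A contrasts rupture vs non-rupture windows over all
windows; Model B, fitted on rupture windows only, estimates the additive
effects of rupture type (withdrawal vs confrontation reference) and of the
minimal-response marker.  Reported alongside the raw estimates are:
standardised betas (refit convention: response z-scored, binary predictors
left on their 0/1 scale — the convention under which a reference-cell
intercept has a non-zero standardised value), Wald 95% CIs, the residual
variance, the ICC, and marginal/conditional R² by the variance-partition
formulation.  `adjust_and_sensitivity()` applies the Bonferroni correction
for the two models (`p_adj = min(1, 2p)`) and refits both with a
square-root transformed response, the usual robustness check for the
positive skew of pause percentages.

`rupture_timecourse()` overlaps ruptures at their annotated onset and
re-bins the *raw pause tracks* in onset-aligned 10-s bins (offsets −20…+29),
not on the session grid — construction tests use ruptures starting
mid-window to pin this down.  Means and standard errors are computed over
ruptures at each offset; a single contributing rupture leaves the SEM
missing rather than zero.  Whether such a figure's error bars should be
over ruptures or over windows is ambiguous in general; over-ruptures is
the documented choice here because the rupture is the sampled unit.

## What the generator plants, and why

The generator emulates ~50-minute two-speaker sessions as alternating
lognormal turns and gaps (heavy right tails match conversational timing),
with the gap mean solved per regime from the renewal identity
`pause_fraction = E[gap] / (E[gap] + E[turn])` — approximate over finite
windows, verified by the calibration tests.  Its defaults are the study
conditions every recovery test assumes:

* **Baseline**: pauses occupy 30.6% of non-rupture time.
* **Rupture cells**: the within-dyad targets are *additive* —
  32.39% for confrontation windows without the marker, +3.22 points for
  withdrawal, +11.67 for the minimal-response marker.  These are the
  fixed effects a window-level mixed model estimates, which makes them the
  right quantities to plant: raw cell means are not invariant to dyad
  composition (see below) while within-dyad effects are.
* **Dyads differ**: a dyad-level baseline shift (sd 6.7 points, the value
  implied by an ICC of 0.08 at a residual variance near 512) is
  standardised to exact zero mean across the corpus, so corpus-level
  targets are hit in expectation by construction.  Each dyad also has its
  own withdrawal propensity (sd 0.12 around 295/516), *correlated* (ρ =
  0.55) with its baseline shift.  This correlation is deliberate: it makes
  raw cell means drift away from the planted within-dyad effects —
  high-pause dyads contribute disproportionately to withdrawal cells —
  reproducing the characteristic gap between raw descriptive tables and
  dyad-adjusted model estimates in clinical samples.  The mixed model
  absorbs the confound; the raw cell means move toward the descriptive
  values the effects were derived from.
* **Rupture mix**: withdrawal fraction 295/516; marker probability 159/295
  given withdrawal and 27/221 given confrontation; episode counts Poisson
  with rate 2 per session; durations lognormal with type means 116.1 s
  (withdrawal) and 133.4 s (confrontation) and matching coefficients of
  variation.  Episodes carrying the marker are planted 2.5× longer than
  unmarked ones of the same type (type-level means preserved exactly): a
  third of episodes but about half of rupture *windows* then carry the
  marker, the composition observed in the clinical annotations, and the
  one that makes window-weighted pooled summaries come out right.
* **Ramp**: for withdrawal ruptures the pause target rises linearly over
  the 25 s before the annotated onset — observers react with a delay, so
  the acoustic change precedes the annotation.  The realised pause process
  additionally lags its target by roughly one turn-gap cycle (~5 s),
  which the recovery tests account for by testing direction, not size.
* **Minimal-response texture**: inside marked episodes the next speaker is
  the therapist with probability √0.7, making the T_T share of pause time
  ≈ 0.7 — the patient skips turns, the therapist carries the dialogue.
  Outside marked episodes speakers continue after a pause with probability
  0.25, so all four patterns occur at baseline.

Rupture placement is uniform with non-overlap enforced by rejection; a
rupture set that stochastically cannot fit is redrawn, and only a session
that cannot host the requested rate at all is rejected with a diagnostic.
Rendered audio is deliberately stylised — harmonic sources at ~110 Hz
(therapist) and ~220 Hz (patient) with amplitude modulation and band noise
over a low noise floor — because the silence detector keys only on
amplitude variability and the diariser on coarse spectral shape.  No
phonetics, no crosstalk, no channel artefacts are simulated; passing the
acoustic tests therefore demonstrates the machinery is correct, not that
field recordings will classify this cleanly.  The diariser's near-perfect
synthetic accuracy in particular is an upper bound with this corpus, not a
claim about clinical audio.

The lognormal/renewal form of within-rupture pause clustering is a
modelling convenience: no distributional form is available for it, and the
recovery checks (which compare means) are insensitive to the choice.

## Problem sizes and reproducibility

Every stochastic stage takes an explicit seed, and a corpus is
reproducible bit-for-bit from its master seed; per-session seeds are
derived so any session can be regenerated in isolation.  The test suite
runs its structural checks on small corpora (6 dyads × 3 sessions × 900 s),
the classifier recovery on 22 × 8 × 1500 s (~480 episodes), and the
mixed-model recovery on 22 dyads × 33 sessions × 3000 s — the clinical
study's design (22 dyads, ~50-minute sessions, ~73k windows) replicated
threefold so that Monte-Carlo error is small against the planted effects
(the withdrawal coefficient's simulation SE drops to ~0.35 points).  The
acceptance script uses the same 22 × 33 × 3000 design.  The only
irreducible noise at that size is dyad composition (22 dyads is the
design), which leaves roughly ±1 point on dyad-weighted summaries.

## Known limitations

* The acoustic path is validated against stylised audio only; real
  boundary-microphone recordings bring overlap, noise and channel drift
  that this corpus does not emulate.
* The 35-feature inventory is a documented default, not the original
  library's list.
* Resolution episodes, rupture significance ratings and observer behaviour
  are out of scope; annotations are consumed as given.
* Raw Table-style cell means in the synthetic corpus match their clinical
  counterparts only approximately (±1–2 points): they are composition-
  dependent quantities and the generator plants composition only through
  the dyad-propensity correlation above.
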