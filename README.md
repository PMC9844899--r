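# pausemark

Speech pauses as an audio-only window on alliance ruptures in dyadic
psychotherapy.

Observer-based rupture coding (e.g. with the Rupture Resolution Rating
System) is accurate but so labour-intensive that it rarely scales beyond a
handful of sessions per treatment.  Withdrawal ruptures — the patient
"moving away" from the therapist — are the easiest to miss and have a
simple acoustic shadow: more speech pauses, concentrated in a particular
speaker-switching pattern.  `pausemark` implements a complete pipeline that
turns a single-channel session recording plus sparse human annotations into
that evidence:

1. **Silence detection** — amplitude ranges in 0.01-s windows, a histogram
   binned by Scott's rule (`3.49·sd·n^(-1/3)`), a cut-off at a histogram
   valley, applied to 0.1-s windows.
2. **Speaker diarisation** — 35 acoustic features per 0.2-s window (MFCC
   means/SDs, F0, energy, spectral shape), a random-forest classifier
   trained on a ≥5-minute labelled learning set, utterance-level majority
   vote.
3. **Speaker-switching patterns** — every pause becomes `P_P`, `P_T`,
   `T_P` or `T_T` according to the speakers around it.
4. **Windowing** — 10-s windows with exact (conservation-tested) pause
   apportioning, joined with rupture annotations; per-dyad z-scored
   pattern percentages lagged ±5 windows give 44 features per window.
5. **Statistics** — linear mixed models with a random intercept per dyad:
   Model A, `pause_pct ~ rupture`, over all windows; Model B,
   `pause_pct ~ type + minimal_response`, over rupture windows; Bonferroni
   adjustment and square-root sensitivity refits; an onset-aligned pause
   time course.  A 500-tree random forest (6 variables per split) detects
   windows of ruptures carrying the *minimal-response* marker, reported via
   OOB error, permutation importance and rank-based ROC/AUC on two
   validation variants.

Clinical recordings cannot be shipped, so the package includes a calibrated
synthetic-session generator (`generator_config()`, `generate_corpus()`,
`render_audio()`) that plants the statistical structure the pipeline must
recover — baseline pause share 30.6%, additive rupture-cell effects
(+3.22 points for withdrawal, +11.67 for the marker over a 32.39%
reference), dyad heterogeneity with an ICC near 0.08, marker-carrying
episodes 2.5× longer than unmarked ones, a 25-s pre-onset ramp for
withdrawal ruptures, and pause time concentrated in the T_T pattern inside
marked episodes.  See `vignettes/pausemark-methods.Rmd` for every planted
value and the reasoning behind it.

## Worked example

Generate a small corpus, analyse it through the ground-truth bypass path
(no audio needed), and ask both headline questions:

```r
library(pausemark)

cfg     <- generator_config(n_dyads = 8, sessions_per_dyad = 4,
                            session_length = 1500, seed = 1)
corpus  <- generate_corpus(cfg)
windows <- truth_to_window_table(corpus)

fit_model_b(windows[windows$in_rupture, ])
#> <mixed_model_fit> Model B (rupture type + minimal response) (ok; response pause_pct)
#>                    term estimate std_error std_beta ci_low ci_high  p_value
#>             (Intercept)    31.58      1.98   -0.278  27.69    35.5 6.71e-09
#>  rupture_typewithdrawal     6.80      2.40    0.302   2.10    11.5 4.77e-03
#>     minimal_responseyes     8.84      2.48    0.393   3.97    13.7 4.01e-04
#>   sigma2 435.91 | ICC 0.040 | N_dyads 8 | observations 599
#>   marginal R2 0.091 / conditional R2 0.128

feats <- add_lags(zscore_by_dyad(windows))
sp    <- split_ruptures(feats[feats$in_rupture, ], seed = 2)
model <- train_rupture_classifier(sp$train, seed = 3)
evaluate_classifier(model, sp$validation, feats[!feats$in_rupture, ])
#> <classifier_report> OOB 9.22% | AUC (ruptures only) 0.998 | AUC (+non-ruptures) 0.996
#>   top feature: z_T_T_lag_p1
```

Reading the output: rupture windows in this small corpus hold 31.6% pauses
in the reference cell (confrontation, no marker); withdrawal windows add
6.8 points and marker-carrying windows 8.8 points (both significant; at
this corpus size the coefficients carry standard errors of ~2.4 points —
larger corpora centre them on the planted 3.22 and 11.67).  The marker
classifier separates marked from unmarked rupture windows almost perfectly
on synthetic data, and its most informative feature is a `T_T` lag —
pauses framed by therapist speech — matching the planted mechanism in
which the patient skips speaking turns.

For the full audio path, `run_pipeline(pipeline_config(use_truth = FALSE,
...), out_dir)` renders audio, detects pauses, diarises, and writes every
table, model report and a hashed run manifest to `out_dir`.

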