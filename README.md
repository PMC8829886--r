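# neurofocus

Tools for studying how background audio affects human focus with a
four-channel consumer EEG headband. The package reimplements an end-to-end
brain-decoding analysis as a tested R pipeline driven by a synthetic-data
generator with known planted structure, so every stage — preprocessing,
feature extraction, per-participant decoding, condition statistics, and a
focus-from-audio model — can be validated without access to raw recordings.

It is written for researchers who work with wearable EEG (AF7/AF8/TP9/TP10
at 256 Hz), self-reported affective labels, and audio stimuli, and who need
a reproducible reference implementation of this class of pipeline.

## What the pipeline computes

1. **Preprocessing** — zero-phase 0.5–70 Hz band-pass + 60 Hz notch per
   channel; 5 s segments sliding by 200 ms (96% overlap, one decoded value
   per 200 ms → a 5 Hz trace; a 30 min task gives 8,976 segments);
   headband QC (raw SD > 500 µV ⇒ misplaced channel); gyroscope motion
   gating of calibration segments; blink counting on the frontal channels.
2. **Features** — 124 per segment: 28 Welch band powers over the bands
   0.5–4, 4–8, 8–12.5, 12.5–30, 30–47, 52–70, 30–70 Hz; 14 symmetric-channel
   power ratios; 16 interactions per channel (α/δ, β/θ, θ/α, and the
   engagement index β/(α+θ)); 42 pairwise inter-channel band correlations;
   24 time-domain statistics — winsorized at mean ± 2 SD.
3. **Decoding** — task-mean features with self-reports form the focus-ranked
   ledger (51 × 4 × 4 = 816 rows at the study's post-exclusion design);
   an ensemble of random-forest regressors trained on random 80% participant
   subsets; per participant, the held-out model with the best calibration
   Pearson r decodes the Preferred Task at 5 Hz, Gaussian-smoothed
   (σ = 2 s); evaluation by ROC/AUC against self-reports binarized at 0.4.
4. **Group statistics** — per-participant median focus per condition →
   one-way repeated-measures ANOVA, Holm-corrected paired post hocs, and a
   per-second paired t-test whose runs of p < .05 are kept only if they beat
   the 95th percentile of maximum run lengths over 1000 sign-flip
   permutations.
5. **Audio** — 50 ms frames sliding by 25 ms → 34 descriptors + deltas = 68
   frame features; mean and SD over 30 s windows → 136 sound properties;
   standardized PCA to 95% variance; linear regression with backward
   elimination (smallest mean |standardized weight| across folds drops
   first) under song-stratified cross-validation (whole songs held out,
   14 train / 4 validation at an 18-song set); song and genre focus
   rankings.

The synthetic generator plants an alpha-suppression / beta-enhancement
coupling between a latent focus profile and the EEG, blink and motion
artifacts at stated rates, condition offsets on the latent profile, and a
linear brightness-to-focus map in the audio — so recovery of each is a
measurable acceptance surface. See `vignettes/focus-decoding-methods.Rmd`
for the full model and every design decision.

## Worked example

A small end-to-end run (6 participants, 2 min Preferred Tasks, 18 synthetic
songs) is scripted in `analysis/01_simulate.R` … `05_validation.R`; each
driver prints what it found and writes tables under `results/`. The core of
it, by hand:

```r
library(neurofocus)

cfg <- default_config(seed = 1)          # all pipeline constants in one place
state <- run_pipeline("simulate", cfg)   # cohort + songs with planted truth
state <- run_pipeline("decode", cfg, state = state)
state <- run_pipeline("stats", cfg, state = state)

rs <- sapply(split(state$decoded$traces, state$decoded$traces$participant),
             function(d) cor(d$focus, d$latent))
median(rs)
state$stats$anova
head(state$stats$timeseries)
```

Running the drivers prints (seed 1):

```
cohort: 6 participants x 4 sessions, conditions balanced: TRUE
songs: 18 (120 s each), planted focus targets in [0.02, 0.96]

ledger: 92 focus-ranked tasks
ensemble: 25 models on 5-participant subsets
decoded-vs-latent Pearson r: median 0.973 (range 0.905-0.983)
Preferred-Task halves vs self-report: AUC 0.993, accuracy 0.958, r 0.933

repeated-measures ANOVA per subgroup:
       group n     F df1 df2        p
         all 6  9.50   3  15 0.000922
     working 4 19.58   3   9 0.000278

Holm-corrected paired post hocs:
                 pair mean_diff      t df       p  p_adj reject
   silence-soundscape   -0.1375 -4.333  5 0.00748 0.0449   TRUE

per-second permutation run-length tests (percent of task significant):
                 pair percent         segments
   silence-soundscape    85.8          0.3-2.0
 playlistA-soundscape    76.7 0.3-1.1; 1.2-2.0

backward elimination: best mean validation r = 0.994 with 9 components
genre mean scores (sorted):   bright 0.714 / lofi 0.289
window-level low/high classification: accuracy 0.917, AUC 0.989
```

(Excerpted; the drivers print the full tables and write them under
`results/`.)

Read: the decoded 5 Hz traces track the latent focus profiles the generator
planted (median Pearson r across participants), the repeated-measures ANOVA
detects the planted condition offsets on this small cohort, and the
run-length-corrected time-series test marks the seconds where the
soundscape condition separates from silence. The audio driver then ranks
songs and genres by predicted focus; with focus planted as a linear
function of spectral brightness, bright songs score high and the planted
genre ordering is recovered.

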