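# glomsep

Odor pattern separation analysis for honeybee antennal-lobe calcium imaging.

`glomsep` is a tidyverse-native R pipeline for ratiometric (FURA-2) imaging
studies of olfactory learning in the honeybee antennal lobe (AL), paired with
M17 muscle electrophysiology as the behavioral memory readout. It takes
dual-wavelength fluorescence movies (or pre-extracted glomerular traces) plus
spike-time tables, and answers, per bee and per cohort: how fast do the
population responses to a trained odor (CS+) and a new odor separate, how
many glomeruli respond to each stimulus, how strong are the dominant
glomeruli, how stable is the response across extinction trials, and do the
conditioned M17 responses confirm learning.

## The statistics at the core

For a bee with glomerular response vectors $a(t), b(t) \in \mathbb{R}^k$
(baseline-subtracted ratio signals $\Delta R$ for two stimuli), the
**pattern separation trace** is the per-frame Euclidean distance

$$d(t) = \lVert a(\cdot,t) - b(\cdot,t) \rVert_2 ,$$

summarized in the **early window** 81–160 ms after odor onset (exactly the
second post-onset frame at 12.5 Hz double frames), and thresholded against
baseline: a bee shows **distinct patterns** if $d(t)$ exceeds the baseline
mean + 3 SD within the first 160 ms. A glomerulus is **responsive** if its
trace exceeds its own pre-onset mean + 3 SD for two consecutive odor frames;
the **dominant glomeruli** are the two most active during the response peak
(240–800 ms), pooled by averaging. M17 responses are baseline-normalized
spike rates, `odor_count/4s − baseline_count/5s`. Cohort contrasts run
through a normality-gated workflow (Shapiro–Wilk and F-test gates selecting
Student's t, Mann–Whitney U or Wilcoxon signed-rank) with pooled-SD Cohen's
d and the 0.2/0.5/0.8 effect-size bands.

Upstream, glomerular ROIs are segmented from the movies by per-pixel
Z-scoring, Gaussian smoothing, PCA, and a convex-cone factorization (greedy
extreme-ray selection with non-negative projection assignment), after rigid
phase-correlation movement correction and F340/F380 ratio computation with
first-40-frame baseline subtraction.

A first-class synthetic generator (`synth_config()`, `synth_cohort()`,
`render_movie()`, `synth_m17_cohort()`) emulates the full recording and
cohort structure — 200 frames at 80 ms, 15 glomeruli, 2×2
(paired/unpaired × inhibitor/solvent) design with realistic group sizes —
and plants treatment effects at calibrated magnitudes (the early-window
separation deficit is planted at Cohen's d = 1.408 by a closed-form moment
calibration), so every stage of the pipeline is testable against ground
truth.

## Worked example

```r
library(glomsep)

cfg <- synth_config(seed = 1)          # the default study conditions
res <- run_pipeline(pipeline_config(seed = 1, synth = cfg))
res$report
#> <cohort_report> 41 comparisons at alpha = 0.05, 12 significant (uncorrected)
#>    id                                 test_used     p_value effect_size_d
#>  1 early_separation_paired            mann-whitney 2.15e- 2         1.39
#>  2 distinct_paired                    mann-whitney 1.61e- 2         1.25
#>  3 responders_new_paired              t            2.26e- 3         1.81
#>  ...
#>  8 m17_csplus_vs_oil_paired_solvent   paired t     1.43e-16         5.11
#> 11 m17_new_paired                     mann-whitney 7.39e- 6        -1.93
#> 12 m17_ext6_paired                    mann-whitney 2.19e- 8        -3.40
```

The report reads exactly like the planted biology: the paired-group
early-window separation deficit is detected (d = 1.39, large), fewer
glomeruli respond to the new odor under the inhibitor, the M17 CS+ response
towers over mineral oil in the paired group (learning), the inhibitor
elevates the new-odor M17 response (generalization; negative d means
inhibitor > solvent) and slows extinction (`m17_ext6_paired`). Unpaired-arm
imaging contrasts stay non-significant except the planted extinction drift.

Single-bee objects pipe into the same metrics:

```r
bt <- generate_bee_traces(cfg, 1, "paired", "solvent")
dt <- distance_trace(bt$traces$csplus, bt$traces$new)
dt
#> <distance_trace> csplus vs new, 200 frames, baseline 0.0549 +/- 0.0099
early_separation(dt)      # 0.098 -- dissimilarity rises above 0.1 at onset
is_distinct(dt)           # TRUE
responsive_glomeruli(bt$traces$new)
#> <responder_summary> new: 9/15 glomeruli responsive (60.0%)
autoplot(dt)              # separation trace with odor window and 3xSD line
```

M17 memory scores (subtractive normalization, Hz over a ~1 Hz baseline):

```r
dplyr::filter(res$memory_scores, group == "paired",
              stimulus %in% c("csplus", "new", "oil"))
#>   group  treatment stimulus     n   mean   sem
#> 1 paired inhibitor csplus      19  6.23  0.344
#> 2 paired inhibitor new         19  3.58  0.279
#> 3 paired inhibitor oil         19 -0.132 0.154
#> 4 paired solvent   csplus      26  6.25  0.309
#> 5 paired solvent   new         26  1.66  0.155
#> 6 paired solvent   oil         26 -0.050 0.147
```

Real data enter at any stage boundary: movies via `read_movie()` (TIFF +
JSON sidecar), hand-traced ROI label images via `glom_map()`, trace tables
via `read_traces_csv()`/`cohort_metrics()`, spike tables via `m17_rates()`,
and a custom comparison set via `read_manifest_yaml()`/`run_report()`.

## Package layout

- `R/` — synth (generator), preproc (registration, ratio), segment
  (PCA + convex cone), metrics (separation, responders, dominant glomeruli,
  extinction), ephys (M17 rates), stats/report (test selection, manifest),
  pipeline (orchestration), plots.
- `tests/testthat/` — unit, property and acceptance suites (fixtures are
  generated in code).
- `vignettes/glomsep-methods.Rmd` — the methods vignette: models,
  assumptions, parameter choices, calibration details, limitations.
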