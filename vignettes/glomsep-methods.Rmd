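---
title: "Methods: quantifying odor pattern separation in the honeybee antennal lobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying odor pattern separation in the honeybee antennal lobe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glomsep)
```

## The scientific problem

Appetitive olfactory conditioning reshapes how the honeybee antennal lobe
(AL) — the insect analog of the olfactory bulb — represents odors. Projection
neurons innervating the AL's glomeruli can be imaged in vivo with the
ratiometric calcium dye FURA-2: calcium influx raises fluorescence excited at
340 nm and lowers it at 380 nm, so the ratio F340/F380 reports activity
independently of dye concentration. After training (a rewarded odor, CS+)
under pharmacological manipulation of DNA methyltransferases, the questions
this package quantifies are:

1. How quickly do the population responses to the CS+ and a new odor become
   distinct (*pattern separation*), measured frame by frame as the Euclidean
   distance between the two glomerular response vectors?
2. How many glomeruli respond to each stimulus (3x-SD responder rule)?
3. How strongly do the two most responsive ("dominant") glomeruli respond?
4. How stable is the CS+ representation over six unreinforced extinction
   trials?
5. Does the conditioned response (spike rate of the proboscis muscle M17)
   confirm learning?

Cohorts follow a 2x2 design: training *group* (paired CS-US, which forms
long-term memory, vs unpaired stimulation control) crossed with *treatment*
(Dnmt inhibitor vs solvent).

## Pipeline overview

```
dual-wavelength movies (TIFF)  --register-->  co-registered movies
  --ratio, baseline-->  dR movies  --Z-score, blur, PCA, cone-->  glomerulus map
  --pixel averaging-->  per-glomerulus traces  --metrics-->  per-bee metric table
M17 spike times (CSV)  --windowed rates-->  per-bee rate table
both tables  --comparison manifest-->  cohort report (JSON/Markdown)
```

Each arrow is a documented file-format boundary (TIFF + JSON sidecar, long
CSV tables), so real recordings can enter at any stage — e.g. manually traced
ROIs skip detection via `glom_map()`, and pre-extracted trace tables enter at
`cohort_metrics()`.

## Coordinate model and preprocessing

Frames are half-open intervals `[i*dt, (i+1)*dt)` with `dt = 80` ms (12.5 Hz
double frames). A 16 s recording has 200 frames; odor onset at 4 s is frame
50 and the odor lasts 50 frames. The early analysis window of 81–160 ms after
onset is therefore exactly the second post-onset frame; at other frame rates
`early_separation()` averages all frames fully contained in the window.

Movement correction (`register_movie()`) estimates one rigid translation per
frame by FFT phase cross-correlation of the channel-mean image against a
reference frame (the middle baseline frame), then applies the same corrective
shift to both wavelength channels; `align_movies()` repeats this once per
stimulus movie against the first movie. Shifts are integer-pixel by default
(`subpixel = TRUE` enables parabolic peak refinement with bilinear
resampling). Shifts are applied circularly; for real, non-circular motion the
wrapped border band (at most the maximum shift, typically 1–3 px) should be
regarded as invalid. Registration precedes the ratio because the ratio of
shifted channels is not the shift of the ratio near structure edges.

`compute_ratio()` divides the channels pixel-wise and subtracts, per pixel,
the mean ratio of the first 40 frames (the pre-odor baseline), yielding
\(\Delta R\). A zero or negative F380 anywhere is a hard error with pixel
coordinates — inside stained tissue this indicates data corruption, and
silent clipping would bias every downstream metric.

## Glomerulus segmentation

`detect_glomeruli()` implements an activity-based source separation:

1. per-pixel Z-score of the time series concatenated across all stimulus
   movies (concatenation gives one map valid for every stimulus);
2. spatial Gaussian smoothing, sigma = 2 px, to stabilize the geometry;
3. PCA of the pixels-by-time matrix, retaining `min(30, numerical rank)`
   components by default;
4. convex-cone factorization: generators are chosen greedily as the pixels
   with maximal residual norm after Gram–Schmidt deflation of previously
   chosen generators — the extreme rays of the data cone. Every pixel is
   then assigned to the generator with the largest non-negative projection
   coefficient of its **unsmoothed** Z-scored series onto the generator's
   PCA-reconstructed time course, if that coefficient reaches 0.5 of the
   generator's self-coefficient *and* the raw series correlates at least 0.5
   with the time course;
5. connected-component cleanup discards components under 20 px.

Two choices deserve justification. Assignment on unsmoothed data keeps ROI
boundaries sharp: after blurring, the corner pixels of a compact ROI fall
below any coefficient threshold that still excludes the outside halo, so
pixel-accurate recovery is impossible on the smoothed field. The correlation
gate exists because smoothing makes neighboring *noise* pixels cohere: a
noise-selected generator is a local average its neighbors correlate with
weakly (roughly the central smoothing weight, about 0.2) but systematically,
enough to pass a purely relative coefficient threshold as a ~30 px disc.
Genuine glomerular pixels correlate near 1 with their glomerulus' time
course at realistic noise, so the gate removes spurious components without
touching real ones. On pure-noise input the detector returns an empty map.

`extract_traces()` is the unweighted pixel mean of \(\Delta R\) per labeled
area and frame.

## Response metrics

- **Separation trace** (`distance_trace()`): per-frame Euclidean distance
  between two stimuli's glomerular vectors, un-normalized by default (the
  scale on which background dissimilarity sits near 0.05 with ~15 glomeruli);
  a `sqrt(n)` normalization is available for cross-bee comparisons with
  unequal glomerulus counts. Baseline mean and SD of the distance over all
  pre-onset frames are stored alongside.
- **Early separation** (`early_separation()`): the distance in the 81–160 ms
  window, where pattern separation effects are most prominent.
- **Distinctness** (`is_distinct()`): the bee shows distinct patterns if the
  distance exceeds `baseline_mean + 3*SD` at any frame within 160 ms of
  onset. The mean offset is included (the rule would otherwise trigger on any
  positive baseline bias); the degenerate noise-free case (zero mean and SD)
  counts any positive distance as distinct, with a message.
- **Responders** (`responsive_glomeruli()`): a glomerulus responds if its
  trace exceeds its own pre-onset mean + 3 SD for at least 2 consecutive
  odor-window frames. The run-length requirement suppresses single-frame
  noise spikes; at the default noise level it holds the per-glomerulus false
  positive rate well under 2%.
- **Dominant glomeruli** (`dominant_glomeruli()`): glomeruli are ranked by
  their mean response to a reference stimulus over the peak window — frames
  onset+3 to onset+10 (240–800 ms), chosen to cover the response plateau
  after the 3-frame rise while excluding onset transients; the window is
  configurable and reported. The top two are pooled by averaging; rank ties
  break toward the lower glomerulus index for determinism.
- **Extinction stability** (`extinction_stability()`): distance of each
  extinction trial's pattern from trial 1; zero means a perfectly stable
  response.

`cohort_metrics()` computes all of the above per bee from the tabular trace
format and returns a long tibble ready for the report stage.

## M17 spike analysis

`normalized_rate()` converts windowed spike counts (5 s baseline, 4 s odor)
into `odor_rate - baseline_rate` in Hz. Subtraction is the default because
baseline rates near zero (mineral oil trials run at ~1 Hz) make ratios
explode; divisive normalization is available by flag and returns `NA` with a
warning on silent baselines. The subtractive estimator is exactly unbiased
for the Poisson rate difference.

## Test-selection workflow

`compare_groups()` reproduces the normality-gated workflow: Shapiro–Wilk on
each sample (on the paired differences for paired designs) and an F-test of
equal variances (independent designs only); if all diagnostics exceed p =
0.05 a pooled-variance Student's t-test is used, otherwise Mann–Whitney U
(independent) or Wilcoxon signed-rank (paired). The 0.05 gate is a fixed
convention; the diagnostics are always reported so the gate is auditable.
Constant samples or n < 3 fall back to the non-parametric path with a
warning. Rank tests use the exact distribution for n <= 25 without ties and
the tie-corrected normal approximation with continuity correction otherwise.
Cohen's d (pooled-SD form) is attached to every comparison with the
0.2/0.5/0.8 category bands; no multiple-testing correction is applied, but
the report carries the comparison count so users can apply their own.
Empirically the workflow holds its type-I error within [0.03, 0.07] at
alpha = 0.05 on Gaussian nulls.

The default comparison manifest (`default_manifest()`) runs treatment
contrasts within each training group for every imaging metric and the M17
new-odor and last-extinction contrasts, plus within-bee CS+ vs mineral-oil
contrasts per cell. Tails follow the convention that directional tests are
used only where a prior directional hypothesis exists: the CS+ vs oil
contrast (conditioned responding), the distinct-proportion contrast, and the
early-window separation contrast (the inhibitor is hypothesized to *reduce*
separation) are one-tailed; everything else is two-tailed.

## The synthetic cohort generator

`synth_config()` fixes the study conditions: 200 frames at 80 ms, odor at
4–8 s, 15 glomeruli, 172x130 px movies, response amplitudes of 0.1 ratio
units, trace noise SD 0.01 (which places the baseline population-distance
floor near 0.05), and imaging cohort sizes 7/10 (paired solvent/inhibitor)
and 6/10 (unpaired); M17 cohort sizes are 26/19/13/15. Per-bee traces are
`amplitude x kernel + N(0, noise_sd)` with a fixed kernel (3-frame linear
rise, plateau, 1 s exponential decay after offset — response shape is not a
study parameter, so it is fixed but configurable).

Planted treatment effects are confined to where the study design expects
them:

- the new-odor pattern diverges from the CS+ pattern along a mixing ramp
  `w(t)` reaching 1 after 2 frames, slowed by `separation_lag = 2` in the
  paired-inhibitor cell only (early-window separation deficit);
- each glomerulus responds to the new odor with probability
  `responder_fraction_new` (0.6 paired-solvent, 0.27 paired-inhibitor, 0.5
  unpaired — the planted responder-count effect);
- `dominant_gain_new = 0.5` scales the whole new-odor pattern in the
  paired-inhibitor cell, which scales the measured dominant-glomeruli peak
  by exactly that factor (scaling only the top two would merely reshuffle
  the ranking);
- `extinction_drift = 0.01` ratio units per trial raises the dominant CS+
  amplitudes across extinction trials in the unpaired-inhibitor cell only.
- the M17 generator emits homogeneous Poisson spikes at 7 Hz for the paired
  CS+, 1 Hz for mineral oil and baseline, an elevated new-odor rate under
  the inhibitor, and extinction rates decaying faster under the solvent.

Bee-to-bee variability is a per-bee response gain `g ~ N(1, sigma)`
(truncated at 0.2). `sigma` is not hand-picked: it is solved in closed form
so that the planted early-window deficit between the paired arms equals a
target Cohen's d of 1.408 (a large effect, the magnitude the analysis is
meant to resolve) given the cohort sizes. The calibration models the
early-window distance estimator as noncentral chi (mean
`sqrt(lambda^2 + k*tau^2)`, delta-method variance) and uses exact Bernoulli
moments of the responder-set distance; it depends only on the configuration,
never on test outcomes. Mixtures are the elementwise maximum of the
component patterns — a saturation approximation that keeps the mixture
within the component range.

`render_movie()` maps traces to pixels: ROI pixels of glomerulus k carry
`F340 = B * (1 + alpha*dR)` and `F380 = B * (1 - beta*dR)`, a per-ROI
staining factor common to both channels (the anatomy registration locks
onto; it cancels in the ratio), optional Gaussian read noise, and an optional
circular integer drift schedule. The default `beta = 0` makes the
ratio-minus-baseline readout equal the planted `dR` identically, so
preprocessing can be tested against ground truth at 1e-9; `beta > 0`
emulates the bidirectional FURA response at the cost of a (known, monotone)
nonlinearity `(alpha+beta)dR / (1 - beta*dR)`.

### What the generator does and does not emulate

It reproduces the recording geometry, cohort structure, effect placement and
realistic magnitudes. It does **not** model the AL inhibitory network,
calcium dynamics, bleaching, non-rigid motion, temporally correlated or
signal-dependent noise, or glomerulus-identity correspondence across bees.
Passing recovery tests therefore demonstrates that the analysis is correct
and calibrated under its stated assumptions — not that those assumptions
exhaust real FURA data.

## Numerical choices and degenerate inputs

- Distances use exact sums of squares; a brute-force oracle agrees to 1e-12.
- Division by zero in the ratio, empty ROIs, mismatched glomerulus sets,
  out-of-range windows, negative rates, and unknown cohort labels are hard
  errors; constant frames in registration warn and return zero shift.
- The distinctness rule's false-positive rate on pure noise is bounded
  analytically: with baseline statistics estimated from m frames the
  per-frame exceedance is the prediction-interval tail
  `P(t_{m-1} > 3*sqrt(m/(m+1)))` inflated by the exact chi-vs-normal tail
  ratio (the null distance is chi-distributed, slightly right-skewed), union
  over the two horizon frames: 0.0085 under the default conditions. A naive
  `P(chi > mu+3sd)` bound ignores threshold estimation and is too small.
- All randomness derives from one master seed; each bee owns a derived
  stream, so any bee can be regenerated in isolation and runs are
  byte-identical (`run_pipeline()` writes no timestamps into the report).

## Problem sizes used in the checks

The packaged checks run: 100 random instances for the distance oracle; all
5551 2x2 tables with margins <= 12 for the Fisher oracle; one 15-glomerulus
movie pair (172x130 px, 200 frames) per noise level for segmentation
recovery; 10^4 pure-noise glomeruli and 4x10^4 null cohorts for detector
calibration; 200 simulated cohorts per arm for effect recovery; and 10^4
Gaussian-null comparisons for the workflow's type-I error. These sizes give
Monte-Carlo standard errors comfortably below the margins being tested.

## Known limitations

- Rigid translation only; rotation, scaling and non-rigid deformation are
  out of scope (bees with strong movement are excluded upstream in practice).
- The cone factorization is an activity-based method: a glomerulus silent in
  every recorded stimulus is invisible to it by construction.
- Glomeruli are not matched to anatomical atlas identities; pooling across
  bees therefore uses only within-bee constructs (top-2 selection,
  proportions, distances).
- The exact segmentation defaults (k = 30 components, sigma = 2 px, 20 px
  minimum, 0.5 thresholds) were chosen for ~50 px glomeruli at the default
  image scale and should be revisited for other magnifications.
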