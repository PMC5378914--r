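test_that("mineral oil with zero noise gives identically zero traces", {
  bt <- generate_bee_traces(exact_cfg(), 1, "paired", "solvent")
  expect_identical(max(abs(bt$traces$oil$values)), 0)
})

test_that("generator is bitwise deterministic under a fixed seed", {
  cfg <- quick_cfg()
  b1 <- generate_bee_traces(cfg, 3, "unpaired", "inhibitor")
  b2 <- generate_bee_traces(cfg, 3, "unpaired", "inhibitor")
  expect_identical(b1, b2)
  expect_false(identical(
    b1$traces$csplus$values,
    generate_bee_traces(cfg, 4, "unpaired", "inhibitor")$traces$csplus$values))
})

test_that("noise-free distance at full mixing equals the planted pattern gap", {
  # ramp reaches w = 1 at post-onset frame 5; kernel is on plateau there
  cfg <- exact_cfg(ramp_frames = 6, separation_lag = 1)
  bt <- generate_bee_traces(cfg, 1, "paired", "inhibitor")
  dt <- distance_trace(bt$traces$csplus, bt$traces$new)
  expect_equal(dt$d[cfg$odor_onset_frame + 5 + 1],
               sqrt(sum((bt$truth$pattern_A - bt$truth$pattern_B)^2)),
               tolerance = 1e-12)
})

test_that("larger separation_lag strictly slows early separation", {
  early <- function(lag) {
    cfg <- exact_cfg(separation_lag = lag, responder_fraction_new = 1)
    bt <- generate_bee_traces(cfg, 1, "paired", "inhibitor")
    early_separation(distance_trace(bt$traces$csplus, bt$traces$new))
  }
  vals <- vapply(c(1, 2, 4), early, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("unknown group or treatment labels are rejected", {
  expect_error(generate_bee_traces(quick_cfg(), 1, "sideways", "solvent"))
  expect_error(generate_bee_traces(quick_cfg(), 1, "paired", "caffeine"))
})

test_that("config invariants are enforced", {
  expect_error(synth_config(n_glomeruli = 0), "n_glomeruli")
  expect_error(synth_config(noise_sd = -0.1), "noise_sd")
  expect_error(synth_config(responder_fraction_new = 1.2), "responder_fraction_new")
  expect_error(synth_config(odor_onset = 15, odor_duration = 4,
                            n_frames = 200, frame_period = 0.08),
               "odor window")
})

test_that("calibrated bee gain puts the paired early-window contrast at the target d", {
  # moment check on the generator's own bees (no observation pipeline):
  # many bees per arm, compare realized standardized difference to target
  cfg <- synth_config(seed = 5)
  sim_arm <- function(treatment, ids) {
    vapply(ids, function(i) {
      bt <- generate_bee_traces(cfg, i, "paired", treatment)
      early_separation(distance_trace(bt$traces$csplus, bt$traces$new))
    }, numeric(1))
  }
  x <- sim_arm("solvent", 1:150)
  y <- sim_arm("inhibitor", 151:300)
  d <- cohens_d(x, y)
  expect_gt(d, 1.408 * 0.75)
  expect_lt(d, 1.408 * 1.35)
})

test_that("synth_cohort produces the full tabular cohort with ground truth", {
  cfg <- quick_cfg()
  tr <- synth_cohort(cfg)
  expect_setequal(unique(tr$stimulus), stimulus_labels())
  expect_equal(length(unique(tr$bee)), sum(cfg$n_bees))
  expect_equal(nrow(tr),
               sum(cfg$n_bees) * 10 * cfg$n_glomeruli * cfg$n_frames)
  expect_length(attr(tr, "truth"), sum(cfg$n_bees))
})

test_that("extinction drift raises dominant amplitudes only in unpaired-inhibitor", {
  cfg <- exact_cfg(extinction_drift = 0.02)
  drifted <- generate_bee_traces(cfg, 1, "unpaired", "inhibitor")
  flat <- generate_bee_traces(cfg, 1, "paired", "solvent")
  peak <- function(bt, j) {
    dominant_glomeruli(bt$traces[[paste0("ext", j)]], bt$traces$ext1)$peak_value
  }
  drift_peaks <- vapply(1:6, function(j) peak(drifted, j), numeric(1))
  flat_peaks <- vapply(1:6, function(j) peak(flat, j), numeric(1))
  expect_true(all(diff(drift_peaks) > 0))
  expect_equal(max(abs(diff(flat_peaks))), 0, tolerance = 1e-12)
})

# ---- movie rendering -------------------------------------------------------

test_that("rendered ratio is constant without signal, noise and drift", {
  cfg <- exact_cfg()
  tr <- mk_traces(matrix(0, 5, 120), "oil", onset = 50, dur = 40)
  mv <- render_movie(tr, NULL, cfg, b340 = 800, b380 = 400)
  r <- mv$f340 / mv$f380
  expect_equal(max(abs(r - 2)), 0, tolerance = 1e-12)
})

test_that("planted dR = 0.1 with alpha = beta = 1 gives pixel ratio 1.1/0.9", {
  cfg <- exact_cfg()
  vals <- matrix(0, 5, 120); vals[1, 60] <- 0.1
  tr <- mk_traces(vals, "csplus", onset = 50, dur = 40)
  labs <- layout_rois(cfg$image_shape, 5)
  mv <- render_movie(tr, list(roi_labels = labs), cfg, alpha = 1, beta = 1)
  px <- which(labs == 1)[1]
  ij <- arrayInd(px, dim(labs))
  expect_equal(mv$f340[ij[1], ij[2], 60] / mv$f380[ij[1], ij[2], 60],
               1.1 / 0.9, tolerance = 1e-12)
})

test_that("a drift step translates subsequent frames exactly", {
  cfg <- exact_cfg()
  bt <- generate_bee_traces(cfg, 1, "paired", "solvent")
  mv <- render_movie(bt$traces$csplus, NULL, cfg,
                     drift = data.frame(frame = 100, dy = 2, dx = 0))
  plain <- render_movie(bt$traces$csplus, NULL, cfg)
  expect_identical(mv$f340[, , 100], plain$f340[, , 100])
  shifted <- glomsep:::shift_matrix(plain$f340[, , 101], 2, 0)
  expect_identical(mv$f340[, , 101], shifted)
})

test_that("gain/amplitude combinations driving F380 <= 0 are rejected", {
  cfg <- exact_cfg()
  vals <- matrix(0, 5, 120); vals[1, 60] <- 0.9
  tr <- mk_traces(vals, "csplus", onset = 50, dur = 40)
  expect_error(render_movie(tr, NULL, cfg, beta = 2), "F380")
})

test_that("movie inversion: extracting ROI ratio traces recovers planted dR to 1e-9", {
  cfg <- exact_cfg()
  bt <- generate_bee_traces(cfg, 2, "paired", "solvent")
  labs <- layout_rois(cfg$image_shape, cfg$n_glomeruli)
  mv <- render_movie(bt$traces$csplus, list(roi_labels = labs), cfg)
  rm_ <- compute_ratio(mv, 40)
  tr <- extract_traces(glom_map(labs), rm_)
  expect_lt(max(abs(tr$values - bt$traces$csplus$values)), 1e-9)
})

# ---- spikes ----------------------------------------------------------------

test_that("zero rates give zero spikes", {
  cfg <- quick_cfg(m17 = list(baseline = 0, oil = 0))
  rec <- generate_spikes(cfg, "paired", "solvent", "oil")
  expect_length(rec$spike_times, 0)
})

test_that("paired/solvent CS+ odor counts match the 7 Hz Poisson mean", {
  cfg <- synth_config(seed = 2)
  counts <- vapply(1:10000, function(i) {
    rec <- generate_spikes(cfg, "paired", "solvent", "csplus", bee_id = i)
    sum(rec$spike_times >= 5 & rec$spike_times < 9)
  }, numeric(1))
  # Poisson(28): empirical mean within 3 standard errors
  se <- sqrt(28 / length(counts))
  expect_lt(abs(mean(counts) - 28), 3 * se)
})

test_that("spike generation is deterministic per bee and stimulus", {
  cfg <- quick_cfg()
  r1 <- generate_spikes(cfg, "unpaired", "inhibitor", "ext3", bee_id = 7)
  r2 <- generate_spikes(cfg, "unpaired", "inhibitor", "ext3", bee_id = 7)
  expect_identical(r1$spike_times, r2$spike_times)
})

test_that("negative configured rates are rejected", {
  expect_error(synth_config(m17 = list(baseline = -1)), "non-negative")
})
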