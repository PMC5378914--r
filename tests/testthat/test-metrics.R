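# Distance trace --------------------------------------------------------------

test_that("distance matches the brute-force oracle on random matrices", {
  set.seed(101)
  for (i in 1:100) {
    g <- sample(2:20, 1); f <- sample(60:120, 1)
    on <- sample(20:40, 1)
    a <- mk_traces(matrix(rnorm(g * f), g, f), "csplus", onset = on, dur = 10)
    b <- mk_traces(matrix(rnorm(g * f), g, f), "new", onset = on, dur = 10)
    expect_lt(max(abs(distance_trace(a, b)$d - brute_distance(a$values, b$values))),
              1e-12)
  }
})

test_that("identical traces give zero distance and a 3-4-5 pair gives 0.1", {
  a <- mk_traces(matrix(rnorm(5 * 100), 5, 100))
  expect_equal(max(distance_trace(a, a)$d), 0)
  x <- matrix(0, 2, 60); y <- matrix(0, 2, 60)
  y[, 55] <- c(0.06, 0.08)
  dt <- distance_trace(mk_traces(x, "csplus", onset = 50, dur = 10),
                       mk_traces(y, "new", onset = 50, dur = 10))
  expect_equal(dt$d[55], 0.1, tolerance = 1e-14)
})

test_that("distance is invariant to a common glomerulus permutation and scales with c", {
  set.seed(102)
  a <- matrix(rnorm(6 * 80), 6, 80); b <- matrix(rnorm(6 * 80), 6, 80)
  p <- sample(6)
  d1 <- distance_trace(mk_traces(a, onset = 40, dur = 10),
                       mk_traces(b, "new", onset = 40, dur = 10))$d
  d2 <- distance_trace(mk_traces(a[p, ], onset = 40, dur = 10),
                       mk_traces(b[p, ], "new", onset = 40, dur = 10))$d
  expect_equal(d1, d2, tolerance = 1e-12)
  d3 <- distance_trace(mk_traces(3 * a, onset = 40, dur = 10),
                       mk_traces(3 * b, "new", onset = 40, dur = 10))$d
  expect_equal(d3, 3 * d1, tolerance = 1e-12)
})

test_that("normalization divides by sqrt(n_glomeruli) and mismatches are rejected", {
  a <- mk_traces(matrix(1, 4, 60), onset = 40, dur = 10)
  b <- mk_traces(matrix(0, 4, 60), "new", onset = 40, dur = 10)
  expect_equal(distance_trace(a, b, normalize = TRUE)$d[1], 1)
  expect_equal(distance_trace(a, b)$d[1], 2)
  c3 <- mk_traces(matrix(0, 3, 60), "new", onset = 40, dur = 10)
  expect_error(distance_trace(a, c3), "glomerulus sets")
})

# Early separation -------------------------------------------------------------

test_that("early separation returns the 81-160 ms frame(s)", {
  d_const <- mk_traces(matrix(0.3, 3, 100), onset = 50, dur = 40)
  z <- mk_traces(matrix(0, 3, 100), "new", onset = 50, dur = 40)
  expect_equal(early_separation(distance_trace(d_const, z)), 0.3 * sqrt(3))
  # 40 ms frames: mean of relative frames 2 and 3
  a <- matrix(0, 1, 200); a[1, 103] <- 1; a[1, 104] <- 3   # rel frames 2, 3 at onset 100
  dt <- distance_trace(mk_traces(a, onset = 100, dur = 40, frame_period = 0.04),
                       mk_traces(matrix(0, 1, 200), "new", onset = 100, dur = 40,
                                 frame_period = 0.04))
  expect_equal(early_separation(dt), 2)
})

test_that("solvent bees separate faster than inhibitor bees in the early window", {
  cfg <- exact_cfg(responder_fraction_new = 1)
  es <- function(tr) {
    bt <- generate_bee_traces(cfg, 1, "paired", tr)
    early_separation(distance_trace(bt$traces$csplus, bt$traces$new))
  }
  expect_gt(es("solvent"), es("inhibitor"))
})

# Distinctness ------------------------------------------------------------------

test_that("distinctness thresholds at baseline mean + 3 SD", {
  set.seed(103)
  base <- rnorm(50, 1, 0.1)
  mk_dt <- function(post_level) {
    d <- c(base, rep(post_level, 50))
    structure(list(d = d, frame_period = 0.08, odor_onset_frame = 50L,
                   odor_duration_frames = 50L, baseline_mean = mean(base),
                   baseline_sd = sd(base), normalized = FALSE,
                   stimuli = c("csplus", "new"), bee = NA),
              class = "distance_trace")
  }
  thr <- mean(base) + 3 * sd(base)
  expect_false(is_distinct(mk_dt(mean(base) + 2.9 * sd(base))))
  expect_true(is_distinct(mk_dt(thr + 0.01)))
})

test_that("noise-free bees with a nonzero pattern difference are distinct", {
  cfg <- exact_cfg(responder_fraction_new = 1)
  bt <- generate_bee_traces(cfg, 1, "paired", "solvent")
  dt <- distance_trace(bt$traces$csplus, bt$traces$new)
  expect_message(flag <- is_distinct(dt), "distinct")
  expect_true(flag)
})

test_that("a planted fraction of separating bees yields that proportion distinct", {
  # 7 of 10 noise-free bees have a pattern difference in the early window
  flags <- vapply(1:10, function(i) {
    vals_a <- matrix(0, 4, 100)
    vals_b <- vals_a
    if (i <= 7) vals_b[1, 52] <- 0.2                 # rel frame 1
    dt <- distance_trace(mk_traces(vals_a, onset = 50, dur = 40),
                         mk_traces(vals_b, "new", onset = 50, dur = 40))
    suppressMessages(is_distinct(dt))
  }, logical(1))
  expect_equal(mean(flags), 0.7)
})

# Responder rule -----------------------------------------------------------------

test_that("a 6-sigma plateau responder is detected, silent traces are not", {
  set.seed(104)
  sd0 <- 0.01
  vals <- matrix(rnorm(3 * 150, 0, sd0), 3, 150)
  vals[1, 61:110] <- vals[1, 61:110] + 6 * sd0
  tr <- mk_traces(vals, onset = 60, dur = 50)
  rs <- responsive_glomeruli(tr)
  expect_true(rs$responsive[1])
  zero <- mk_traces(matrix(0, 3, 150), onset = 60, dur = 50)
  expect_equal(responsive_glomeruli(zero)$n_responsive, 0L)
})

test_that("pure-noise false-positive rate stays at or below 2 percent", {
  set.seed(105)
  fp <- 0L; total <- 0L
  for (r in 1:40) {
    tr <- mk_traces(matrix(rnorm(50 * 200, 0, 0.01), 50, 200), onset = 50, dur = 50)
    fp <- fp + responsive_glomeruli(tr)$n_responsive
    total <- total + 50L
  }
  expect_lte(fp / total, 0.02)
})

test_that("responder preconditions are enforced", {
  tr <- mk_traces(matrix(0, 2, 20), onset = 3, dur = 5)
  expect_error(responsive_glomeruli(tr), "pre-onset")
})

# Dominant glomeruli ----------------------------------------------------------

test_that("dominant selection takes the two strongest, ties to the lower index", {
  amps <- c(0.3, 0.2, 0.05, 0.01)
  kern <- c(rep(0, 50), rep(1, 50))
  tr <- mk_traces(amps %o% kern, onset = 50, dur = 50)
  dr <- dominant_glomeruli(tr)
  expect_equal(dr$glomerulus_ids, c(1L, 2L))
  expect_equal(dr$peak_value, mean(c(0.3, 0.2)))
  tied <- mk_traces(c(0.3, 0.2, 0.2) %o% kern, onset = 50, dur = 50)
  expect_equal(dominant_glomeruli(tied)$glomerulus_ids, c(1L, 2L))
  expect_error(dominant_glomeruli(mk_traces(matrix(0, 1, 100), onset = 50, dur = 50)),
               "2 glomeruli")
})

test_that("halved dominant gain halves the noise-free new-odor peak", {
  peak <- function(gain) {
    cfg <- exact_cfg(responder_fraction_new = 1, dominant_gain_new = gain,
                     ramp_frames = 1)
    bt <- generate_bee_traces(cfg, 1, "paired", "inhibitor")
    dominant_glomeruli(bt$traces$new, bt$traces$new)$peak_value
  }
  expect_equal(peak(c(paired_inhibitor = 0.5, paired_solvent = 1,
                      unpaired_solvent = 1, unpaired_inhibitor = 1)) /
                 peak(1), 0.5, tolerance = 0.02)
})

# Extinction stability ----------------------------------------------------------

test_that("identical extinction trials give zero distances", {
  tr <- mk_traces(matrix(rnorm(4 * 100), 4, 100), "ext1", onset = 50, dur = 40)
  trials <- lapply(paste0("ext", 1:4), function(s) {
    t2 <- tr; t2$stimulus <- s; t2
  })
  dts <- extinction_stability(trials)
  expect_length(dts, 3L)
  expect_equal(max(vapply(dts, function(d) max(d$d), numeric(1))), 0)
})

test_that("a linear per-trial drift on two glomeruli grows as sqrt(2)*(j-1)*delta", {
  delta <- 0.02
  kern <- c(rep(0, 50), rep(1, 50))
  trials <- lapply(1:5, function(j) {
    amps <- c(0.3, 0.25, 0.1, 0.05)
    amps[1:2] <- amps[1:2] + delta * (j - 1)
    mk_traces(amps %o% kern, paste0("ext", j), onset = 50, dur = 50)
  })
  dts <- extinction_stability(trials)
  peaks <- vapply(dts, function(d) d$d[60], numeric(1))
  expect_equal(peaks, sqrt(2) * (1:4) * delta, tolerance = 1e-12)
})

# Cohort wrapper ------------------------------------------------------------------

test_that("cohort_metrics produces the full per-bee metric table", {
  cfg <- quick_cfg()
  tr <- synth_cohort(cfg)
  m <- cohort_metrics(tr, frame_period = cfg$frame_period,
                      odor_onset_frame = cfg$odor_onset_frame,
                      odor_duration_frames = cfg$odor_duration_frames)
  expect_setequal(unique(m$metric),
                  c("early_separation", "odor_separation", "distinct",
                    "pct_responders", "dominant_peak_ref_csplus",
                    "dominant_peak_ref_new", "dominant_peak_ref_ext1",
                    "extinction_distance"))
  expect_equal(length(unique(m$bee)), sum(cfg$n_bees))
  expect_true(all(m$value[m$metric == "pct_responders"] >= 0 &
                    m$value[m$metric == "pct_responders"] <= 100))
  expect_true(all(m$value[m$metric == "distinct"] %in% c(0, 1)))
})
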