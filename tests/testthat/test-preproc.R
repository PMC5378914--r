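# Frame/time mapping ---------------------------------------------------------

test_that("time-to-frame mapping follows the half-open frame convention", {
  expect_equal(frame_of_time(4.0, 0.08, 200), 50)
  expect_equal(frame_of_time(0, 0.08, 200), 0)
  expect_equal(frame_of_time(0.0799, 0.08, 200), 0)
  expect_equal(time_of_frame(50, 0.08), 4)
  expect_error(frame_of_time(-1, 0.08, 200), "out of range")
  expect_error(frame_of_time(16.1, 0.08, 200), "out of range")
})

test_that("the 81-160 ms window is exactly one frame at 80 ms, two at 40 ms", {
  expect_equal(glomsep:::window_rel_frames(0.08, 0.16, 0.08), 1L)
  expect_equal(glomsep:::window_rel_frames(0.08, 0.16, 0.04), c(2L, 3L))
  expect_equal(glomsep:::window_rel_frames(0, 0.16, 0.08), c(0L, 1L))
})

# Ratio computation -----------------------------------------------------------

test_that("constant channels yield identically zero delta_r", {
  f340 <- array(2, dim = c(4, 5, 60)); f380 <- array(1, dim = c(4, 5, 60))
  mv <- dual_movie(f340, f380, 0.08, 50, 10)
  rm_ <- compute_ratio(mv, 40)
  expect_equal(max(abs(rm_$delta_r)), 0, tolerance = 1e-12)
  # baseline invariant: per-pixel mean over baseline frames is ~0
  bl <- apply(rm_$delta_r[, , rm_$baseline_frames + 1L], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-9)
})

test_that("a 0.1 ratio step during odor is recovered exactly", {
  f340 <- array(1, dim = c(3, 3, 100))
  f380 <- array(1, dim = c(3, 3, 100))
  f340[2, 2, 51:100] <- 1.1
  mv <- dual_movie(f340, f380, 0.08, 50, 50)
  rm_ <- compute_ratio(mv, 40)
  expect_equal(rm_$delta_r[2, 2, 60], 0.1, tolerance = 1e-12)
  expect_equal(rm_$delta_r[1, 1, 60], 0, tolerance = 1e-12)
})

test_that("baseline must precede odor onset", {
  f <- array(1, dim = c(3, 3, 100))
  ok <- dual_movie(f, f, 0.08, 50, 10)
  expect_s3_class(compute_ratio(ok, 40), "ratio_movie")
  early <- dual_movie(f, f, 0.08, 30, 10)
  expect_error(compute_ratio(early, 40), "odor onset")
})

test_that("zero F380 pixels are rejected with coordinates", {
  f340 <- array(1, dim = c(3, 3, 60))
  f380 <- array(1, dim = c(3, 3, 60))
  f380[2, 3, 10] <- 0
  mv <- dual_movie(f340, f380, 0.08, 50, 5)
  expect_error(compute_ratio(mv, 40), "row 2, col 3")
})

# Registration ----------------------------------------------------------------

test_that("a drift-free movie registers with all-zero shifts", {
  cfg <- exact_cfg()
  bt <- generate_bee_traces(cfg, 1, "paired", "solvent")
  mv <- render_movie(bt$traces$csplus, NULL, cfg)
  reg <- register_movie(mv)
  expect_true(all(reg$shifts$dy == 0 & reg$shifts$dx == 0))
  expect_identical(reg$movie$f340, mv$f340)
})

test_that("planted integer drift is recovered and corrected exactly", {
  cfg <- exact_cfg()
  bt <- generate_bee_traces(cfg, 1, "paired", "solvent")
  clean <- render_movie(bt$traces$csplus, NULL, cfg)
  drifted <- render_movie(bt$traces$csplus, NULL, cfg,
                          drift = data.frame(frame = 100, dy = 2, dx = 0))
  reg <- register_movie(drifted)
  expect_true(all(reg$shifts$dy[1:100] == 0))
  expect_true(all(reg$shifts$dy[101:120] == -2 & reg$shifts$dx[101:120] == 0))
  expect_equal(reg$movie$f340, clean$f340, tolerance = 1e-12)
  # idempotence
  reg2 <- register_movie(reg$movie)
  expect_true(all(reg2$shifts$dy == 0 & reg2$shifts$dx == 0))
})

test_that("a single-frame movie registers as identity", {
  f <- array(runif(12), dim = c(3, 4, 1))
  mv <- dual_movie(f, f + 1, 0.08, 0, 1)
  reg <- register_movie(mv, reference_frame = 0)
  expect_equal(nrow(reg$shifts), 1L)
  expect_equal(c(reg$shifts$dy, reg$shifts$dx), c(0, 0))
})

test_that("all-zero frames register with zero shift and a warning", {
  f <- array(0, dim = c(4, 4, 3))
  mv <- dual_movie(f, f + 1, 0.08, 2, 1)
  w <- capture_warnings(reg <- register_movie(mv, reference_frame = 0))
  expect_true(all(grepl("undefined", w)))
  expect_true(all(reg$shifts$dy == 0))
})

test_that("between-movie alignment undoes a constant offset", {
  cfg <- exact_cfg()
  bt <- generate_bee_traces(cfg, 1, "paired", "solvent")
  m1 <- render_movie(bt$traces$csplus, NULL, cfg)
  m2 <- render_movie(bt$traces$new, NULL, cfg,
                     drift = data.frame(frame = 0, dy = 3, dx = -1))
  al <- align_movies(list(m1, m2))
  expect_equal(c(al$shifts$dy[2], al$shifts$dx[2]), c(-3, 1))
  ref <- render_movie(bt$traces$new, NULL, cfg)
  expect_equal(al$movies[[2]]$f340, ref$f340, tolerance = 1e-12)
})
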