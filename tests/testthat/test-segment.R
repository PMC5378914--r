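# Helper: build co-registered ratio movies for one synthetic bee.
bee_ratio_movies <- function(cfg, stims = c("csplus", "new"), bee = 1,
                             group = "paired", treatment = "solvent") {
  bt <- generate_bee_traces(cfg, bee, group, treatment)
  labs <- layout_rois(cfg$image_shape, cfg$n_glomeruli)
  movs <- lapply(bt$traces[stims], function(tr) {
    compute_ratio(render_movie(tr, list(roi_labels = labs), cfg), 40)
  })
  list(movies = movs, labels = labs, bee = bt)
}

test_that("three well-separated noise-free glomeruli are recovered at Jaccard 1", {
  cfg <- exact_cfg(n_glomeruli = 3, responder_fraction_new = 1)
  s <- bee_ratio_movies(cfg)
  map <- detect_glomeruli(s$movies)
  expect_equal(map$n_glomeruli, 3L)
  ov <- map_overlap(map, s$labels)
  expect_equal(ov$jaccard, rep(1, 3))
})

test_that("pure-noise movies yield an empty map", {
  set.seed(21)
  arr <- array(rnorm(40 * 60 * 100, 0, 0.01), dim = c(40, 60, 100))
  f380 <- array(1000, dim = dim(arr))
  mv <- dual_movie(1000 + arr, f380, 0.08, 50, 40)
  rm_ <- compute_ratio(mv, 40)
  expect_warning(map <- detect_glomeruli(rm_, max_generators = 10), "empty|min_size")
  expect_equal(map$n_glomeruli, 0L)
})

test_that("noisy recovery finds most planted glomeruli", {
  cfg <- quick_cfg(noise_sd = 0.02, bee_scale_sd = 0, responder_fraction_new = 1)
  s <- bee_ratio_movies(cfg)
  map <- detect_glomeruli(s$movies)
  ov <- map_overlap(map, s$labels)
  expect_gte(sum(ov$jaccard >= 0.6), cfg$n_glomeruli - 1)
})

test_that("recovery degrades monotonically with noise", {
  jac <- vapply(c(0, 0.01, 0.05), function(ns) {
    cfg <- quick_cfg(noise_sd = ns, bee_scale_sd = 0, responder_fraction_new = 1)
    s <- bee_ratio_movies(cfg)
    mean(map_overlap(detect_glomeruli(s$movies), s$labels)$jaccard)
  }, numeric(1))
  expect_true(all(diff(jac) <= 1e-9))
})

test_that("permuting input movie order leaves the pixel partition unchanged", {
  cfg <- exact_cfg(n_glomeruli = 4, responder_fraction_new = 1)
  s <- bee_ratio_movies(cfg, stims = c("csplus", "new", "mix"))
  m1 <- detect_glomeruli(s$movies)
  m2 <- detect_glomeruli(rev(s$movies))
  # same partition up to label identity
  expect_equal(m1$n_glomeruli, m2$n_glomeruli)
  for (k in seq_len(m1$n_glomeruli)) {
    pix <- m1$labels == k
    other <- unique(m2$labels[pix])
    expect_length(other, 1L)
    expect_equal(sum(m2$labels == other), sum(pix))
  }
})

test_that("explicit k_components above the numerical rank is rejected", {
  cfg <- exact_cfg(n_glomeruli = 3, responder_fraction_new = 1)
  s <- bee_ratio_movies(cfg, stims = "csplus")
  expect_error(detect_glomeruli(s$movies, k_components = 50), "rank")
})

# Trace extraction ------------------------------------------------------------

test_that("trace extraction averages ROI pixels", {
  labs <- matrix(0L, 4, 4); labs[1:2, 1:2] <- 1L
  arr <- array(0, dim = c(4, 4, 60))
  arr[1, 1, 50] <- 0.1; arr[1, 2, 50] <- 0.1; arr[2, 1, 50] <- 0.1; arr[2, 2, 50] <- 0.1
  rm_ <- glomsep:::new_ratio_movie(arr, 0:39, 0.08, 45, 10, "csplus")
  tr <- extract_traces(glom_map(labs), rm_)
  expect_equal(tr$values[1, 50], 0.1)
  expect_equal(tr$values[1, 1], 0)
})

test_that("extraction noise variance scales as noise_sd^2 / n_pixels", {
  set.seed(31)
  n_pix <- 25; n_f <- 10000; sd0 <- 0.05
  labs <- matrix(0L, 10, 10); labs[3:7, 3:7] <- 1L
  arr <- array(0, dim = c(10, 10, n_f))
  idx <- which(labs == 1L)
  for (p in idx) {
    ij <- arrayInd(p, c(10, 10))
    arr[ij[1], ij[2], ] <- rnorm(n_f, 0, sd0)
  }
  rm_ <- glomsep:::new_ratio_movie(arr, 0:39, 0.08, 5000, 100, "csplus")
  tr <- extract_traces(glom_map(labs), rm_)
  expect_equal(var(tr$values[1, ]), sd0^2 / n_pix, tolerance = 0.2)
})

test_that("user-supplied label maps bypass detection (manual override)", {
  labs <- matrix(0L, 6, 6); labs[1:3, 1:3] <- 2L; labs[5:6, 5:6] <- 7L
  map <- glom_map(labs)
  expect_equal(map$n_glomeruli, 2L)           # relabeled contiguously
  expect_setequal(unique(as.vector(map$labels)), c(0L, 1L, 2L))
})

test_that("shape mismatches and empty maps are rejected", {
  arr <- array(0, dim = c(4, 4, 10))
  rm_ <- glomsep:::new_ratio_movie(arr, 0:4, 0.08, 5, 2, "csplus")
  expect_error(extract_traces(glom_map(matrix(0L, 5, 5)), rm_), "shape")
  expect_error(extract_traces(glom_map(matrix(0L, 4, 4)), rm_), "no glomeruli")
})
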