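# Small, fast configurations shared across tests.

# Deterministic miniature cohort config: 5 glomeruli, 120 frames,
# odor 4-7.2 s (frames 50..89), tiny image.
quick_cfg <- function(n_bees = 2, n_glomeruli = 5, seed = 11, ...) {
  synth_config(n_bees = n_bees, n_glomeruli = n_glomeruli, n_frames = 120,
               odor_onset = 4, odor_duration = 3.2,
               image_shape = c(40, 60), seed = seed, ...)
}

# Noise-free, bee-deterministic variant for exactness tests.
exact_cfg <- function(...) {
  quick_cfg(noise_sd = 0, bee_scale_sd = 0, ...)
}

# Bare glom_traces from a matrix with standard timing.
mk_traces <- function(values, stimulus = "csplus", frame_period = 0.08,
                      onset = 50, dur = 50) {
  glom_traces(values, stimulus = stimulus, frame_period = frame_period,
              odor_onset_frame = onset, odor_duration_frames = dur)
}

# Independent brute-force Euclidean distance (explicit loops; the oracle for
# distance_trace).
brute_distance <- function(a, b) {
  n_f <- ncol(a)
  out <- numeric(n_f)
  for (t in seq_len(n_f)) {
    s <- 0
    for (g in seq_len(nrow(a))) s <- s + (a[g, t] - b[g, t])^2
    out[t] <- sqrt(s)
  }
  out
}

# Independent exhaustive two-sided Fisher p by hypergeometric enumeration
# (sums the probabilities of all tables with the observed margins whose
# probability does not exceed the observed one, with the standard 1e-7
# relative tolerance for floating-point ties).
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  a_min <- max(0, c1 - r2); a_max <- min(r1, c1)
  probs <- stats::dhyper(a_min:a_max, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
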