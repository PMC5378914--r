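#' Configuration of the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: 200 double frames at
#' 12.5 Hz (80 ms per frame), odor onset at 4 s lasting 4 s, ~15 glomeruli
#' per animal, response amplitudes of ~0.1 ratio units over a background
#' dissimilarity near 0.05, and imaging group sizes of 7/10 (paired
#' solvent/inhibitor) and 6/10 (unpaired). Treatment effects are planted only
#' where the study reports them: (i) a slower CS+/new-odor separation ramp in
#' the paired-inhibitor cell, (ii) fewer new-odor responders in that cell,
#' (iii) weaker new-odor dominant-glomerulus amplitude there, and (iv) a
#' per-trial extinction drift of the dominant glomeruli in the
#' unpaired-inhibitor cell.
#'
#' Bee-to-bee variability enters as a per-bee global response gain
#' `g ~ N(1, bee_scale_sd)`. When `bee_scale_sd` is `NULL` it is calibrated
#' in closed form (moments of the noncentral-chi distance estimator and of
#' the Bernoulli responder sets) so that the planted early-window separation
#' deficit between the paired arms equals `target_effect_d` (default 1.408,
#' a large effect) by construction.
#'
#' @param n_bees Bees per group x treatment cell: scalar or named vector over
#'   `paired_solvent, paired_inhibitor, unpaired_solvent, unpaired_inhibitor`.
#' @param n_glomeruli Glomeruli per bee (default 15).
#' @param frame_period Seconds per double frame (default 0.08).
#' @param n_frames Frames per recording (default 200, i.e. 16 s).
#' @param odor_onset,odor_duration Odor timing in seconds (defaults 4 and 4).
#' @param image_shape Pixel dimensions `c(H, W)` of rendered movies
#'   (default `c(130, 172)`).
#' @param response_amplitude Peak glomerular response in ratio units
#'   (default 0.1).
#' @param noise_sd Gaussian trace noise per glomerulus and frame
#'   (default 0.01, placing the baseline population-distance floor near 0.05).
#' @param separation_lag Multiplier on the separation ramp length in the
#'   paired-inhibitor cell (default 2; > 1 means slower separation).
#' @param ramp_frames Frames over which the new-odor pattern diverges from
#'   the CS+ pattern in unaffected cells (default 2).
#' @param responder_fraction_new Per-cell probability that a glomerulus
#'   responds to the new odor.
#' @param dominant_gain_new Per-cell multiplicative factor on the new-odor
#'   response amplitudes (default 0.5 in paired-inhibitor, 1 elsewhere).
#'   Scaling the whole new-odor pattern scales the measured
#'   dominant-glomeruli peak by exactly this factor; scaling only the top
#'   two would let previously weaker glomeruli take over the ranking and
#'   dilute the planted effect.
#' @param extinction_drift Amplitude increment (ratio units per trial) of the
#'   dominant glomeruli across extinction trials in the unpaired-inhibitor
#'   cell (default 0.01).
#' @param target_effect_d Planted Cohen's d of the paired-group early-window
#'   separation deficit (default 1.408).
#' @param bee_scale_sd SD of the per-bee response gain; `NULL` (default)
#'   calibrates it from `target_effect_d`, `0` makes bees deterministic.
#' @param rise_frames,decay_tau Temporal response kernel: linear rise over
#'   `rise_frames` frames (default 3), plateau during odor, exponential decay
#'   with time constant `decay_tau` seconds after offset (default 1).
#' @param m17 Optional overrides for the spike-rate table (see
#'   [m17_odor_rate()]).
#' @param m17_n_bees M17 cohort sizes per cell (defaults 26/19/13/15).
#' @param seed Master RNG seed; every bee derives its own stream from
#'   `(seed, bee index)`.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_bees = c(paired_solvent = 7, paired_inhibitor = 10,
                                    unpaired_solvent = 6, unpaired_inhibitor = 10),
                         n_glomeruli = 15,
                         frame_period = 0.08,
                         n_frames = 200,
                         odor_onset = 4.0,
                         odor_duration = 4.0,
                         image_shape = c(130, 172),
                         response_amplitude = 0.1,
                         noise_sd = 0.01,
                         separation_lag = 2,
                         ramp_frames = 2,
                         responder_fraction_new = c(paired_solvent = 0.6,
                                                    paired_inhibitor = 0.27,
                                                    unpaired_solvent = 0.5,
                                                    unpaired_inhibitor = 0.5),
                         dominant_gain_new = c(paired_solvent = 1,
                                               paired_inhibitor = 0.5,
                                               unpaired_solvent = 1,
                                               unpaired_inhibitor = 1),
                         extinction_drift = 0.01,
                         target_effect_d = 1.408,
                         bee_scale_sd = NULL,
                         rise_frames = 3,
                         decay_tau = 1.0,
                         m17 = list(),
                         m17_n_bees = c(paired_solvent = 26, paired_inhibitor = 19,
                                        unpaired_solvent = 13, unpaired_inhibitor = 15),
                         seed = 1L) {
  cfg <- list(
    n_bees = round(expand_cells(n_bees, "n_bees")),
    n_glomeruli = check_count(n_glomeruli, "n_glomeruli"),
    frame_period = check_scalar_number(frame_period, "frame_period", 0, TRUE),
    n_frames = check_count(n_frames, "n_frames"),
    odor_onset = check_scalar_number(odor_onset, "odor_onset", 0),
    odor_duration = check_scalar_number(odor_duration, "odor_duration", 0, TRUE),
    image_shape = c(check_count(image_shape[1], "image_shape[1]"),
                    check_count(image_shape[2], "image_shape[2]")),
    response_amplitude = check_scalar_number(response_amplitude, "response_amplitude", 0),
    noise_sd = check_scalar_number(noise_sd, "noise_sd", 0),
    separation_lag = check_scalar_number(separation_lag, "separation_lag", 0, TRUE),
    ramp_frames = check_count(ramp_frames, "ramp_frames"),
    responder_fraction_new = expand_cells(responder_fraction_new, "responder_fraction_new"),
    dominant_gain_new = expand_cells(dominant_gain_new, "dominant_gain_new"),
    extinction_drift = check_scalar_number(extinction_drift, "extinction_drift", 0),
    target_effect_d = check_scalar_number(target_effect_d, "target_effect_d", 0),
    rise_frames = check_count(rise_frames, "rise_frames"),
    decay_tau = check_scalar_number(decay_tau, "decay_tau", 0, TRUE),
    m17 = m17_rate_defaults(m17),
    m17_n_bees = round(expand_cells(m17_n_bees, "m17_n_bees")),
    seed = check_count(seed, "seed", min = 0L))
  if (any(cfg$n_bees < 1)) stop_glomsep("`n_bees` must be >= 1 in every cell")
  if (any(cfg$responder_fraction_new < 0 | cfg$responder_fraction_new > 1)) {
    stop_glomsep("`responder_fraction_new` must lie in [0, 1]")
  }
  if (cfg$odor_onset + cfg$odor_duration > cfg$n_frames * cfg$frame_period + 1e-12) {
    stop_glomsep("odor window extends past the recording")
  }
  cfg$odor_onset_frame <- as.integer(round(cfg$odor_onset / cfg$frame_period))
  cfg$odor_duration_frames <- as.integer(round(cfg$odor_duration / cfg$frame_period))
  cfg$bee_scale_sd <- if (is.null(bee_scale_sd)) {
    calibrate_bee_scale_sd(cfg)
  } else {
    check_scalar_number(bee_scale_sd, "bee_scale_sd", 0)
  }
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("<synth_config> %d glomeruli, %d frames @ %.0f ms, odor %g-%g s\n",
                     "  bees/cell: %s; noise_sd %g; planted early-window d %g ",
                     "(bee gain sd %.4f); seed %d\n"),
              x$n_glomeruli, x$n_frames, x$frame_period * 1000, x$odor_onset,
              x$odor_onset + x$odor_duration,
              paste(x$n_bees, collapse = "/"), x$noise_sd, x$target_effect_d,
              x$bee_scale_sd, x$seed))
  invisible(x)
}

# ---- deterministic pattern templates --------------------------------------

# CS+ pattern: a fixed set of responders with graded amplitudes.
base_pattern_a <- function(cfg) {
  n <- cfg$n_glomeruli
  n_a <- max(2L, ceiling(0.4 * n))
  amp <- numeric(n)
  amp[seq_len(n_a)] <- cfg$response_amplitude * seq(1, 0.4, length.out = n_a)
  amp
}

# New-odor candidate amplitudes (every glomerulus can be recruited).
base_pattern_b_profile <- function(cfg) {
  n <- cfg$n_glomeruli
  cfg$response_amplitude * seq(0.95, 0.45, length.out = n)
}

# Temporal response kernel: linear rise, plateau, exponential decay.
response_kernel <- function(cfg) {
  rel <- seq_len(cfg$n_frames) - 1L - cfg$odor_onset_frame
  k <- numeric(cfg$n_frames)
  on <- rel >= 0 & rel < cfg$odor_duration_frames
  k[on] <- pmin(1, (rel[on] + 1) / cfg$rise_frames)
  post <- rel >= cfg$odor_duration_frames
  k[post] <- exp(-(rel[post] - cfg$odor_duration_frames + 1) * cfg$frame_period / cfg$decay_tau)
  k
}

# Mixing ramp w(t): fraction of the new-odor pattern present, reaching 1
# after r frames (r scaled by separation_lag in the paired-inhibitor cell).
mixing_ramp <- function(cfg, cell) {
  r <- cfg$ramp_frames * if (cell == "paired_inhibitor") cfg$separation_lag else 1
  rel <- seq_len(cfg$n_frames) - 1L - cfg$odor_onset_frame
  w <- numeric(cfg$n_frames)
  w[rel >= 0] <- pmin(1, (rel[rel >= 0] + 1) / r)
  w
}

# ---- closed-form calibration of the per-bee gain SD -----------------------
# The early-window metric is the population distance at the second post-onset
# frame: m = g * kappa * w * D + estimator noise, with D = ||A - B|| over the
# Bernoulli responder set. Moments of D come from per-glomerulus independence;
# the distance estimator is treated as noncentral chi with k = n_glomeruli
# dof and per-coordinate noise sd tau = sqrt(2) * noise_sd. bee gain sd is the
# closed-form solution that puts the pooled standardized difference between
# the paired arms at target_effect_d.
calibrate_bee_scale_sd <- function(cfg) {
  kappa <- min(1, 2 / cfg$rise_frames)
  arm <- function(cell) {
    a <- base_pattern_a(cfg)
    b0 <- base_pattern_b_profile(cfg) * cfg$dominant_gain_new[cell]
    f <- cfg$responder_fraction_new[cell]
    ed2 <- sum(f * (a - b0)^2 + (1 - f) * a^2)
    vd2 <- sum(f * (1 - f) * ((a - b0)^2 - a^2)^2)
    vd <- if (ed2 > 0) vd2 / (4 * ed2) else 0
    ed <- sqrt(max(ed2 - vd, 0))
    r <- cfg$ramp_frames * if (cell == "paired_inhibitor") cfg$separation_lag else 1
    w1 <- min(1, 2 / r)
    lam <- kappa * w1 * ed
    tau2 <- 2 * cfg$noise_sd^2
    k <- cfg$n_glomeruli
    h <- sqrt(lam^2 + k * tau2)
    hp <- if (h > 0) lam / h else 0
    vchi <- if (h > 0) (2 * k * tau2^2 + 4 * tau2 * lam^2) / (4 * h^2) else 0
    list(mean = h,
         a = hp^2 * (kappa * w1)^2 * ed2,        # coefficient of sd^2
         b = hp^2 * (kappa * w1)^2 * (ed2 - ed^2) + vchi)
  }
  s <- arm("paired_solvent"); i <- arm("paired_inhibitor")
  n1 <- cfg$n_bees[["paired_solvent"]]; n2 <- cfg$n_bees[["paired_inhibitor"]]
  df <- n1 + n2 - 2
  pool <- function(x1, x2) ((n1 - 1) * x1 + (n2 - 1) * x2) / df
  delta <- s$mean - i$mean
  if (df < 1 || delta <= 0 || cfg$target_effect_d <= 0) return(0)
  v_target <- (delta / cfg$target_effect_d)^2
  sd2 <- (v_target - pool(s$b, i$b)) / pool(s$a, i$a)
  if (!is.finite(sd2)) return(0)
  sqrt(max(sd2, 0))
}

# ---- trace generation ------------------------------------------------------

#' Generate glomerular traces for one synthetic bee
#'
#' Draws the bee's RNG stream from `(seed, bee_id)`, samples its new-odor
#' responder set and per-bee response gain, and returns noise-added
#' \eqn{\Delta R} trace matrices for all ten stimuli together with the ground
#' truth used by recovery tests. Each trace is
#' `amplitude x temporal kernel + N(0, noise_sd)`; the new-odor pattern at
#' frame `t` is `(1 - w(t)) * pattern_A + w(t) * pattern_B` with the ramp `w`
#' slowed by `separation_lag` in the paired-inhibitor cell; mineral oil is
#' noise only; the mixture is the elementwise maximum of the component
#' patterns; extinction trials repeat the CS+ pattern, with the dominant
#' amplitudes drifting upward per trial in the unpaired-inhibitor cell.
#'
#' @param config A [synth_config()].
#' @param bee_id Integer bee index (also keys the bee's RNG stream).
#' @param group `"paired"` or `"unpaired"`.
#' @param treatment `"solvent"` or `"inhibitor"`.
#' @return List with `traces` (named list of [glom_traces()], one per
#'   stimulus) and `truth` (effective patterns, ramp, responder set, gain).
#' @export
generate_bee_traces <- function(config, bee_id, group, treatment) {
  stopifnot(inherits(config, "synth_config"))
  bee_id <- check_count(bee_id, "bee_id")
  cell <- cell_key(group, treatment)
  bee <- sprintf("bee%03d", bee_id)
  withr::with_seed(derive_seed(config$seed, bee_id), {
    n <- config$n_glomeruli
    a <- base_pattern_a(config)
    b0 <- base_pattern_b_profile(config)
    resp <- rbinom(n, 1L, config$responder_fraction_new[cell])
    b <- b0 * config$dominant_gain_new[cell] * resp
    g <- if (config$bee_scale_sd > 0) max(0.2, rnorm(1, 1, config$bee_scale_sd)) else 1
    kern <- response_kernel(config)
    w <- mixing_ramp(config, cell)
    drift_ids <- order(-a)[1:2]

    mk <- function(values, stim) {
      noise <- if (config$noise_sd > 0) {
        matrix(rnorm(length(values), 0, config$noise_sd), nrow(values))
      } else 0
      glom_traces(values + noise, stimulus = stim,
                  frame_period = config$frame_period,
                  odor_onset_frame = config$odor_onset_frame,
                  odor_duration_frames = config$odor_duration_frames,
                  bee = bee, group = group, treatment = treatment)
    }

    traces <- list()
    traces$csplus <- mk(g * (a %o% kern), "csplus")
    traces$new <- mk(g * ((a %o% kern) + ((b - a) %o% (kern * w))), "new")
    traces$oil <- mk(matrix(0, n, config$n_frames), "oil")
    traces$mix <- mk(g * (pmax(a, b) %o% kern), "mix")
    for (j in 1:6) {
      aj <- a
      if (cell == "unpaired_inhibitor") {
        aj[drift_ids] <- aj[drift_ids] + config$extinction_drift * (j - 1)
      }
      traces[[paste0("ext", j)]] <- mk(g * (aj %o% kern), paste0("ext", j))
    }
    truth <- list(bee = bee, group = group, treatment = treatment,
                  pattern_A = g * a, pattern_B = g * b, mixing_ramp = w,
                  bee_gain = g, responders_new = resp,
                  dominant_csplus = drift_ids)
    list(traces = traces, truth = truth)
  })
}

#' Generate the full synthetic imaging cohort
#'
#' Iterates [generate_bee_traces()] over every group x treatment cell and
#' returns the tabular trace format (`bee, group, treatment, stimulus,
#' glomerulus, frame, time, value`). Per-bee ground truth is attached as
#' attribute `"truth"`.
#'
#' @param config A [synth_config()].
#' @return A long tibble of traces.
#' @export
synth_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  rows <- list(); truths <- list()
  idx <- 0L
  for (group in c("paired", "unpaired")) {
    for (treatment in c("solvent", "inhibitor")) {
      cell <- cell_key(group, treatment)
      for (i in seq_len(config$n_bees[[cell]])) {
        idx <- idx + 1L
        bt <- generate_bee_traces(config, idx, group, treatment)
        truths[[bt$truth$bee]] <- bt$truth
        rows[[length(rows) + 1L]] <- dplyr::bind_rows(lapply(bt$traces, as_tibble))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- truths
  out
}

# ---- movie rendering -------------------------------------------------------

#' Deterministic ROI layout for rendered movies
#'
#' Places square glomerular ROIs on a regular grid; every ROI has at least
#' `roi_side^2` contiguous pixels.
#'
#' @param image_shape `c(H, W)` pixel dimensions.
#' @param n_glomeruli Number of ROIs.
#' @param roi_side ROI side length in pixels (default 7, i.e. 49 px).
#' @return Integer label matrix.
#' @export
layout_rois <- function(image_shape, n_glomeruli, roi_side = 7L) {
  h <- image_shape[1]; w <- image_shape[2]
  ncol_g <- ceiling(sqrt(n_glomeruli * w / h))
  nrow_g <- ceiling(n_glomeruli / ncol_g)
  if (nrow_g * (2 * roi_side) > h || ncol_g * (2 * roi_side) > w) {
    stop_glomsep("image %d x %d too small for %d ROIs of side %d",
                 h, w, n_glomeruli, roi_side)
  }
  labels <- matrix(0L, h, w)
  ys <- round(seq(roi_side, h - 2 * roi_side, length.out = nrow_g))
  xs <- round(seq(roi_side, w - 2 * roi_side, length.out = ncol_g))
  k <- 0L
  for (y in ys) for (x in xs) {
    if (k >= n_glomeruli) break
    k <- k + 1L
    labels[y:(y + roi_side - 1L), x:(x + roi_side - 1L)] <- k
  }
  labels
}

#' Render a dual-wavelength movie from glomerular traces
#'
#' FURA-2 forward model: for a pixel in glomerulus `k` at frame `t`,
#' `F340 = B340 * (1 + alpha * dR_k(t))` and
#' `F380 = B380 * (1 - beta * dR_k(t))`; background pixels carry the
#' baselines only. Optional Gaussian read noise and a rigid integer-pixel
#' drift schedule (circular translation) support registration testing. The
#' default `beta = 0` makes the 340/380 ratio minus its baseline equal the
#' planted \eqn{\Delta R} identically; `beta > 0` emulates the bidirectional
#' FURA response, in which case the ratio readout is the monotone transform
#' `(alpha + beta) dR / (1 - beta * dR)` of the planted signal.
#'
#' @param traces A [glom_traces()] for one stimulus.
#' @param truth Optional ground-truth list; `truth$roi_labels` supplies the
#'   label image, otherwise [layout_rois()] is used.
#' @param config A [synth_config()] (provides the image shape).
#' @param b340,b380 Baseline intensities (default 1000).
#' @param alpha,beta Channel gains (defaults 1 and 0).
#' @param stain_contrast Dye-uptake contrast of the glomeruli: pixels of ROI
#'   `k` carry a staining factor `1 + stain_contrast * (0.5 + 0.5 k / n)`
#'   applied to both channels (default 0.5). This gives the frames the
#'   anatomical structure movement correction locks onto; being common to
#'   both channels it cancels exactly in the ratio.
#' @param read_noise_sd Gaussian read noise per pixel and frame (default 0).
#' @param drift Optional data frame `frame` (0-based), `dy`, `dx`: cumulative
#'   translation applied from that frame onward.
#' @return A [dual_movie()].
#' @export
render_movie <- function(traces, truth = NULL, config,
                         b340 = 1000, b380 = 1000, alpha = 1, beta = 0,
                         stain_contrast = 0.5, read_noise_sd = 0, drift = NULL) {
  stopifnot(inherits(traces, "glom_traces"), inherits(config, "synth_config"))
  labels <- truth$roi_labels %||% layout_rois(config$image_shape, nrow(traces$values))
  if (max(labels) != nrow(traces$values)) {
    stop_glomsep("roi_labels (%d ROIs) inconsistent with traces (%d glomeruli)",
                 max(labels), nrow(traces$values))
  }
  if (beta > 0 && any(1 - beta * traces$values <= 0)) {
    stop_glomsep("beta and response amplitude drive F380 <= 0; reduce beta")
  }
  h <- nrow(labels); w <- ncol(labels); n_f <- ncol(traces$values)
  n_roi <- max(labels)
  stain <- matrix(1, h, w)
  idx_by_roi <- lapply(seq_len(n_roi), function(k) which(labels == k))
  for (k in seq_len(n_roi)) {
    stain[idx_by_roi[[k]]] <- 1 + stain_contrast * (0.5 + 0.5 * k / n_roi)
  }
  f340 <- array(0, dim = c(h, w, n_f))
  f380 <- array(0, dim = c(h, w, n_f))
  for (t in seq_len(n_f)) {
    p340 <- matrix(b340, h, w); p380 <- matrix(b380, h, w)
    for (k in seq_len(n_roi)) {
      dr <- traces$values[k, t]
      p340[idx_by_roi[[k]]] <- b340 * (1 + alpha * dr)
      p380[idx_by_roi[[k]]] <- b380 * (1 - beta * dr)
    }
    f340[, , t] <- p340 * stain; f380[, , t] <- p380 * stain
  }
  if (!is.null(drift)) {
    for (r in seq_len(nrow(drift))) {
      fr <- drift$frame[r]
      for (t in (fr + 1L):n_f) {
        f340[, , t] <- shift_matrix(f340[, , t], drift$dy[r], drift$dx[r])
        f380[, , t] <- shift_matrix(f380[, , t], drift$dy[r], drift$dx[r])
      }
    }
  }
  if (read_noise_sd > 0) {
    f340 <- f340 + array(rnorm(length(f340), 0, read_noise_sd), dim = dim(f340))
    f380 <- f380 + array(rnorm(length(f380), 0, read_noise_sd), dim = dim(f380))
    f380[f380 <= 0] <- .Machine$double.eps
  }
  if (any(f380 <= 0)) stop_glomsep("rendered F380 contains non-positive values")
  dual_movie(f340, f380, traces$frame_period, traces$odor_onset_frame,
             traces$odor_duration_frames, traces$stimulus)
}

# ---- M17 spike generation --------------------------------------------------

m17_rate_defaults <- function(overrides = list()) {
  d <- list(baseline = 1,
            csplus_paired = 7, csplus_unpaired = 1.5,
            oil = 1,
            new = c(paired_solvent = 2.5, paired_inhibitor = 4.5,
                    unpaired_solvent = 2, unpaired_inhibitor = 2),
            mix_paired = 5, mix_unpaired = 1.8,
            ext_start = 7, ext_decay_solvent = 0.4, ext_decay_inhibitor = 0.15,
            ext_unpaired = 1.5)
  for (nm in names(overrides)) d[[nm]] <- overrides[[nm]]
  d$new <- expand_cells(d$new, "m17$new")
  rates <- c(unlist(d[c("baseline", "csplus_paired", "csplus_unpaired", "oil",
                        "mix_paired", "mix_unpaired", "ext_start", "ext_unpaired")]),
             d$new)
  if (any(rates < 0)) stop_glomsep("M17 rates must be non-negative")
  d
}

#' Poisson spike rate of the M17 generator
#'
#' Returns the odor-window rate (Hz) for a cohort cell and stimulus. The CS+
#' rate in the paired group defaults to the conditioned-response scale of
#' 7 Hz, mineral oil to 1 Hz; the new-odor rate is elevated under the
#' inhibitor in the paired group (generalization) and extinction-trial rates
#' decay faster under the solvent.
#'
#' @param config A [synth_config()].
#' @param group,treatment Cohort cell.
#' @param stimulus Stimulus label.
#' @return Rate in Hz.
#' @export
m17_odor_rate <- function(config, group, treatment, stimulus) {
  stopifnot(inherits(config, "synth_config"))
  cell <- cell_key(group, treatment)
  m <- config$m17
  stimulus <- match.arg(stimulus, stimulus_labels())
  if (stimulus == "csplus") {
    return(if (group == "paired") m$csplus_paired else m$csplus_unpaired)
  }
  if (stimulus == "oil") return(m$oil)
  if (stimulus == "new") return(m$new[[cell]])
  if (stimulus == "mix") {
    return(if (group == "paired") m$mix_paired else m$mix_unpaired)
  }
  j <- as.integer(sub("ext", "", stimulus))
  if (group == "unpaired") return(m$ext_unpaired)
  decay <- if (treatment == "solvent") m$ext_decay_solvent else m$ext_decay_inhibitor
  m$ext_start * exp(-decay * (j - 1))
}

#' Generate an M17 spike record for one trial
#'
#' Homogeneous Poisson spikes: the 5 s pre-stimulus baseline window at the
#' baseline rate and the 4 s odor window at the stimulus-specific rate from
#' [m17_odor_rate()].
#'
#' @inheritParams m17_odor_rate
#' @param bee_id Integer bee index keying the RNG stream.
#' @return An [m17_record()].
#' @export
generate_spikes <- function(config, group, treatment, stimulus, bee_id = 1L) {
  stopifnot(inherits(config, "synth_config"))
  cell <- cell_key(group, treatment)
  stimulus <- match.arg(stimulus, stimulus_labels())
  rate <- m17_odor_rate(config, group, treatment, stimulus)
  stim_i <- match(stimulus, stimulus_labels())
  withr::with_seed(derive_seed(config$seed, 100000 + bee_id, stim_i), {
    base <- sort(runif(rpois(1, m17_baseline_rate(config) * 5), 0, 5))
    odor <- sort(runif(rpois(1, rate * 4), 5, 9))
    m17_record(c(base, odor), baseline_window = c(0, 5), odor_window = c(5, 9),
               stimulus = stimulus, bee = sprintf("m17bee%03d", bee_id),
               group = group, treatment = treatment)
  })
}

m17_baseline_rate <- function(config) config$m17$baseline

#' Generate the full synthetic M17 cohort
#'
#' One trial per bee and stimulus, in the tabular spike format
#' `bee, group, treatment, stimulus, spike_time`. Trials with zero spikes
#' appear as a single row with `spike_time = NA` so every bee x stimulus
#' combination is represented.
#'
#' @param config A [synth_config()].
#' @return A long tibble of spike times.
#' @export
synth_m17_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  rows <- list(); idx <- 0L
  for (group in c("paired", "unpaired")) {
    for (treatment in c("solvent", "inhibitor")) {
      cell <- cell_key(group, treatment)
      for (i in seq_len(config$m17_n_bees[[cell]])) {
        idx <- idx + 1L
        for (stim in stimulus_labels()) {
          rec <- generate_spikes(config, group, treatment, stim, bee_id = idx)
          st <- if (length(rec$spike_times)) rec$spike_times else NA_real_
          rows[[length(rows) + 1L]] <- tibble(
            bee = rec$bee, group = group, treatment = treatment,
            stimulus = stim, spike_time = st)
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}
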