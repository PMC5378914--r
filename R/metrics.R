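#' Euclidean-distance separation trace between two odor patterns
#'
#' The per-frame dissimilarity of two stimuli's glomerular population
#' vectors: `d(t) = || a(., t) - b(., t) ||_2`, optionally divided by
#' `sqrt(n_glomeruli)` for cross-bee comparability. Baseline mean and SD of
#' `d` over all pre-onset frames calibrate the distinctness criterion.
#'
#' @param a,b [glom_traces()] with identical glomerulus set, frame grid and
#'   odor timing.
#' @param normalize Divide by `sqrt(n_glomeruli)`? Default `FALSE` (raw
#'   distance, the scale on which background dissimilarity is ~0.05).
#' @return An object of class `distance_trace`: per-frame `d`, baseline
#'   statistics, timing, and the stimulus pair.
#' @export
distance_trace <- function(a, b, normalize = FALSE) {
  stopifnot(inherits(a, "glom_traces"), inherits(b, "glom_traces"))
  if (nrow(a$values) != nrow(b$values)) stop_glomsep("glomerulus sets differ")
  if (ncol(a$values) != ncol(b$values)) stop_glomsep("frame grids differ")
  if (a$odor_onset_frame != b$odor_onset_frame ||
      a$frame_period != b$frame_period) {
    stop_glomsep("odor timing differs between the two trace sets")
  }
  d <- sqrt(colSums((a$values - b$values)^2))
  if (normalize) d <- d / sqrt(nrow(a$values))
  pre <- seq_len(a$odor_onset_frame)
  structure(list(
    d = d, frame_period = a$frame_period, odor_onset_frame = a$odor_onset_frame,
    odor_duration_frames = a$odor_duration_frames,
    baseline_mean = mean(d[pre]), baseline_sd = sd(d[pre]),
    normalized = normalize, stimuli = c(a$stimulus, b$stimulus),
    bee = a$bee), class = "distance_trace")
}

#' @export
print.distance_trace <- function(x, ...) {
  cat(sprintf("<distance_trace> %s vs %s, %d frames, baseline %.4f +/- %.4f%s\n",
              x$stimuli[1], x$stimuli[2], length(x$d), x$baseline_mean,
              x$baseline_sd, if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' @method as_tibble distance_trace
#' @export
as_tibble.distance_trace <- function(x, ...) {
  tibble(frame = seq_along(x$d) - 1L,
         time = (seq_along(x$d) - 1L) * x$frame_period,
         d = x$d)
}

#' Early-window pattern separation
#'
#' The distance in the initial odor response: by default the 81--160 ms
#' window after odor onset, which at 80 ms frames is exactly the second
#' post-onset frame. If a different frame period makes the window span
#' several frames, their mean is returned.
#'
#' @param dt A [distance_trace()].
#' @param window Two-element window `c(lo, hi)` in seconds after onset
#'   (default `c(0.08, 0.16)`).
#' @return Scalar distance.
#' @export
early_separation <- function(dt, window = c(0.08, 0.16)) {
  stopifnot(inherits(dt, "distance_trace"))
  rel <- window_rel_frames(window[1], window[2], dt$frame_period)
  frames <- dt$odor_onset_frame + rel + 1L
  if (max(frames) > length(dt$d)) stop_glomsep("early window extends past the recording")
  mean(dt$d[frames])
}

#' Whole-odor-period pattern separation
#'
#' Mean distance over every odor frame (the "entire odor stimulus" summary).
#'
#' @param dt A [distance_trace()].
#' @return Scalar distance.
#' @export
odor_separation <- function(dt) {
  stopifnot(inherits(dt, "distance_trace"))
  frames <- dt$odor_onset_frame + seq_len(dt$odor_duration_frames)
  if (max(frames) > length(dt$d)) stop_glomsep("odor window extends past the recording")
  mean(dt$d[frames])
}

#' Distinct-pattern criterion
#'
#' A bee shows distinct odor patterns if the separation trace exceeds
#' `baseline_mean + 3 * baseline_sd` at any post-onset frame within the first
#' `horizon` seconds (default 160 ms, i.e. the first two post-onset frames at
#' 80 ms). In the degenerate noise-free case (zero baseline mean and SD) any
#' positive distance counts as distinct, with a message.
#'
#' @param dt A [distance_trace()].
#' @param horizon Seconds after onset within which distinctness is assessed.
#' @return Logical flag.
#' @export
is_distinct <- function(dt, horizon = 0.16) {
  stopifnot(inherits(dt, "distance_trace"))
  rel <- window_rel_frames(0, horizon, dt$frame_period)
  frames <- dt$odor_onset_frame + rel + 1L
  frames <- frames[frames <= length(dt$d)]
  if (!length(frames)) stop_glomsep("horizon window extends past the recording")
  peak <- max(dt$d[frames])
  if (dt$baseline_sd == 0 && dt$baseline_mean == 0) {
    if (peak > 0) inform("zero baseline noise: any positive distance counts as distinct")
    return(peak > 0)
  }
  peak > dt$baseline_mean + 3 * dt$baseline_sd
}

#' Responsive glomeruli under the 3x-SD rule
#'
#' A glomerulus counts as responsive to a stimulus if its trace exceeds its
#' own pre-onset mean + 3 SD for at least `k_consecutive` consecutive frames
#' within the odor window (the consecutive-frame requirement suppresses
#' single-frame noise spikes).
#'
#' @param traces A [glom_traces()] with at least 5 pre-onset frames.
#' @param k_consecutive Required run length of supra-threshold frames
#'   (default 2).
#' @return An object of class `responder_summary`: counts, percentage and the
#'   per-glomerulus logical vector.
#' @export
responsive_glomeruli <- function(traces, k_consecutive = 2) {
  stopifnot(inherits(traces, "glom_traces"))
  k_consecutive <- check_count(k_consecutive, "k_consecutive")
  if (traces$odor_onset_frame < 5L) stop_glomsep("need at least 5 pre-onset frames")
  if (traces$odor_duration_frames < 1L) stop_glomsep("odor window is empty")
  pre <- seq_len(traces$odor_onset_frame)
  odor <- traces$odor_onset_frame + seq_len(traces$odor_duration_frames)
  resp <- vapply(seq_len(nrow(traces$values)), function(g) {
    x <- traces$values[g, ]
    thr <- mean(x[pre]) + 3 * sd(x[pre])
    above <- x[odor] > thr
    r <- rle(above)
    any(r$values & r$lengths >= k_consecutive)
  }, logical(1))
  structure(list(stimulus = traces$stimulus,
                 n_responsive = sum(resp), n_total = length(resp),
                 pct = 100 * sum(resp) / length(resp),
                 responsive = resp), class = "responder_summary")
}

#' @export
print.responder_summary <- function(x, ...) {
  cat(sprintf("<responder_summary> %s: %d/%d glomeruli responsive (%.1f%%)\n",
              x$stimulus, x$n_responsive, x$n_total, x$pct))
  invisible(x)
}

#' Dominant-glomeruli response
#'
#' Ranks glomeruli by their mean response to a reference stimulus over the
#' peak window (default 240--800 ms post onset, frames onset+3..onset+10 at
#' 80 ms), selects the top two ("dominant glomeruli", ties broken toward the
#' lower glomerulus index), pools them by averaging, and evaluates the pooled
#' trace of the stimulus of interest.
#'
#' @param traces [glom_traces()] to evaluate.
#' @param reference [glom_traces()] defining the ranking (same glomerulus
#'   set); defaults to `traces` itself.
#' @param peak_window Relative post-onset frame indices of the peak window
#'   (default `3:10`).
#' @return An object of class `dominant_response`: the two glomerulus ids,
#'   the pooled per-frame trace, and `peak_value` (mean of the pooled trace
#'   over the peak window).
#' @export
dominant_glomeruli <- function(traces, reference = traces, peak_window = 3:10) {
  stopifnot(inherits(traces, "glom_traces"), inherits(reference, "glom_traces"))
  if (nrow(reference$values) < 2L) stop_glomsep("need at least 2 glomeruli")
  if (nrow(reference$values) != nrow(traces$values)) stop_glomsep("glomerulus sets differ")
  frames <- reference$odor_onset_frame + peak_window + 1L
  if (max(frames) > ncol(reference$values)) stop_glomsep("peak window extends past the recording")
  score <- rowMeans(reference$values[, frames, drop = FALSE])
  ids <- order(-score)[1:2]                     # order() breaks ties by index
  pooled <- colMeans(traces$values[ids, , drop = FALSE])
  ev_frames <- traces$odor_onset_frame + peak_window + 1L
  structure(list(reference_stimulus = reference$stimulus,
                 stimulus = traces$stimulus,
                 glomerulus_ids = sort(ids),
                 pooled_trace = pooled,
                 peak_window = peak_window,
                 peak_value = mean(pooled[ev_frames]),
                 frame_period = traces$frame_period,
                 odor_onset_frame = traces$odor_onset_frame),
            class = "dominant_response")
}

#' @export
print.dominant_response <- function(x, ...) {
  cat(sprintf("<dominant_response> glomeruli %s (ref %s), peak %.4f on '%s'\n",
              paste(x$glomerulus_ids, collapse = ","), x$reference_stimulus,
              x$peak_value, x$stimulus))
  invisible(x)
}

#' Extinction-trial response stability
#'
#' Distance of each extinction trial's glomerular pattern from the first
#' trial: `0` means a perfectly stable odor response.
#'
#' @param trials List of [glom_traces()] for extinction trials 1..J (J >= 2),
#'   common glomerulus set.
#' @param normalize Passed to [distance_trace()].
#' @return List of [distance_trace()] objects for trials 2..J vs trial 1.
#' @export
extinction_stability <- function(trials, normalize = FALSE) {
  if (length(trials) < 2L) stop_glomsep("need at least 2 extinction trials")
  ng <- vapply(trials, function(t) nrow(t$values), integer(1))
  if (length(unique(ng)) != 1L) stop_glomsep("trials have mismatched glomerulus sets")
  lapply(trials[-1], function(tj) distance_trace(tj, trials[[1]], normalize = normalize))
}

# ---- cohort-level tidy wrapper --------------------------------------------

#' Per-bee response metrics for a whole cohort
#'
#' Data-frame-first wrapper computing every per-bee metric from the tabular
#' trace format: early-window and whole-odor CS+/new separation, the
#' distinct-pattern flag, percent responsive glomeruli per stimulus,
#' dominant-glomeruli peak responses (referenced to the CS+, the new odor and
#' the first extinction trial), and extinction-stability distances at the
#' response peak.
#'
#' @param df Long trace table (`bee, group, treatment, stimulus, glomerulus,
#'   frame, value`).
#' @param frame_period,odor_onset_frame,odor_duration_frames Recording
#'   timing.
#' @param normalize Normalize distances by `sqrt(n_glomeruli)`?
#' @param k_consecutive Responder-rule run length (see
#'   [responsive_glomeruli()]).
#' @param peak_window Relative peak-window frames (see
#'   [dominant_glomeruli()]).
#' @param horizon Distinctness horizon in seconds (see [is_distinct()]).
#' @return Tibble `bee, group, treatment, metric, stimulus, value`.
#' @export
cohort_metrics <- function(df, frame_period = 0.08, odor_onset_frame = 50,
                           odor_duration_frames = 50, normalize = FALSE,
                           k_consecutive = 2, peak_window = 3:10,
                           horizon = 0.16) {
  bees <- traces_from_table(df, frame_period, odor_onset_frame, odor_duration_frames)
  rows <- list()
  add <- function(meta, metric, stimulus, value) {
    rows[[length(rows) + 1L]] <<- tibble(
      bee = meta$bee, group = meta$group, treatment = meta$treatment,
      metric = metric, stimulus = stimulus, value = value)
  }
  for (tb in bees) {
    meta <- tb[[1]][c("bee", "group", "treatment")]
    if (all(c("csplus", "new") %in% names(tb))) {
      dt <- distance_trace(tb$csplus, tb$new, normalize = normalize)
      add(meta, "early_separation", "new", early_separation(dt))
      add(meta, "odor_separation", "new", odor_separation(dt))
      add(meta, "distinct", "new",
          as.numeric(suppressMessages(is_distinct(dt, horizon = horizon))))
    }
    for (s in intersect(stimulus_labels(), names(tb))) {
      add(meta, "pct_responders", s,
          responsive_glomeruli(tb[[s]], k_consecutive)$pct)
    }
    for (ref in intersect(c("csplus", "new", "ext1"), names(tb))) {
      evs <- switch(ref,
                    csplus = c("csplus", "new", "mix"),
                    new = "new",
                    ext1 = paste0("ext", 1:6))
      for (s in intersect(evs, names(tb))) {
        dr <- dominant_glomeruli(tb[[s]], tb[[ref]], peak_window)
        add(meta, paste0("dominant_peak_ref_", ref), s, dr$peak_value)
      }
    }
    exts <- intersect(paste0("ext", 1:6), names(tb))
    if (length(exts) >= 2L) {
      dts <- extinction_stability(tb[exts], normalize = normalize)
      for (j in seq_along(dts)) {
        frames <- dts[[j]]$odor_onset_frame + peak_window + 1L
        add(meta, "extinction_distance", exts[j + 1L], mean(dts[[j]]$d[frames]))
      }
    }
  }
  dplyr::bind_rows(rows)
}
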