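#' Per-glomerulus response time courses
#'
#' A `glom_traces` object holds the baseline-normalized ratio response
#' (\eqn{\Delta R}) of each glomerulus over time for one stimulus
#' presentation: a `n_glomeruli x n_frames` matrix plus timing metadata and
#' optional bee/cohort annotations.
#'
#' @param values Numeric matrix, glomeruli in rows, frames in columns.
#' @param stimulus Stimulus label (see [stimulus_labels()]).
#' @param frame_period Frame duration in seconds.
#' @param odor_onset_frame 0-based odor onset frame.
#' @param odor_duration_frames Number of odor frames.
#' @param bee,group,treatment Optional cohort annotations.
#' @return An object of class `glom_traces`.
#' @export
glom_traces <- function(values, stimulus, frame_period, odor_onset_frame,
                        odor_duration_frames, bee = NA_character_,
                        group = NA_character_, treatment = NA_character_) {
  values <- as.matrix(values)
  if (nrow(values) < 1L) stop_glomsep("need at least one glomerulus")
  if (anyNA(values)) stop_glomsep("trace matrix contains missing values")
  check_scalar_number(frame_period, "frame_period", min = 0, strict_min = TRUE)
  odor_onset_frame <- check_count(odor_onset_frame, "odor_onset_frame", min = 0L)
  odor_duration_frames <- check_count(odor_duration_frames, "odor_duration_frames")
  if (odor_onset_frame + odor_duration_frames > ncol(values)) {
    stop_glomsep("odor window extends past the recording (%d frames)", ncol(values))
  }
  stimulus <- match.arg(stimulus, stimulus_labels())
  structure(
    list(values = values, stimulus = stimulus, frame_period = frame_period,
         odor_onset_frame = odor_onset_frame,
         odor_duration_frames = odor_duration_frames,
         bee = bee, group = group, treatment = treatment),
    class = "glom_traces")
}

#' @export
print.glom_traces <- function(x, ...) {
  cat(sprintf("<glom_traces> %d glomeruli x %d frames @ %.0f ms, stimulus '%s'%s\n",
              nrow(x$values), ncol(x$values), x$frame_period * 1000, x$stimulus,
              if (!is.na(x$bee)) paste0(", bee ", x$bee) else ""))
  invisible(x)
}

#' @method as_tibble glom_traces
#' @export
as_tibble.glom_traces <- function(x, ...) {
  n_g <- nrow(x$values); n_f <- ncol(x$values)
  tibble(
    bee = x$bee, group = x$group, treatment = x$treatment,
    stimulus = x$stimulus,
    glomerulus = rep(seq_len(n_g), times = n_f),
    frame = rep(seq_len(n_f) - 1L, each = n_g),
    time = rep((seq_len(n_f) - 1L) * x$frame_period, each = n_g),
    value = as.vector(x$values))
}

#' Rebuild trace objects from the tabular cohort format
#'
#' The tabular interchange format is a long tibble/CSV with columns
#' `bee, group, treatment, stimulus, glomerulus, frame, value` (optionally
#' `time`). This is the boundary at which pre-extracted glomerular traces from
#' other pipelines can enter the analysis.
#'
#' @param df Long-format data frame of traces.
#' @param frame_period Frame duration in seconds.
#' @param odor_onset_frame,odor_duration_frames Odor timing (0-based frames).
#' @return A named list (one element per bee) of named lists of
#'   [glom_traces()] (one per stimulus).
#' @export
traces_from_table <- function(df, frame_period = 0.08, odor_onset_frame = 50,
                              odor_duration_frames = 50) {
  need <- c("bee", "group", "treatment", "stimulus", "glomerulus", "frame", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_glomsep("traces table is missing columns: %s", paste(miss, collapse = ", "))
  df <- dplyr::arrange(df, .data$bee, .data$stimulus, .data$frame, .data$glomerulus)
  out <- list()
  for (b in unique(df$bee)) {
    db <- df[df$bee == b, ]
    stims <- unique(db$stimulus)
    out[[as.character(b)]] <- stats::setNames(lapply(stims, function(s) {
      ds <- db[db$stimulus == s, ]
      n_g <- length(unique(ds$glomerulus))
      n_f <- length(unique(ds$frame))
      if (nrow(ds) != n_g * n_f) stop_glomsep("bee %s stimulus %s: incomplete frame grid", b, s)
      glom_traces(matrix(ds$value, nrow = n_g, ncol = n_f),
                  stimulus = s, frame_period = frame_period,
                  odor_onset_frame = odor_onset_frame,
                  odor_duration_frames = odor_duration_frames,
                  bee = as.character(b), group = ds$group[1], treatment = ds$treatment[1])
    }), stims)
  }
  out
}

#' Read/write the tabular trace format as CSV
#' @param df Long-format traces tibble.
#' @param path CSV path.
#' @export
write_traces_csv <- function(df, path) {
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
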