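# ggplot2 visualizations for the main result types.

#' @describeIn distance_trace Plot the separation trace with the odor window
#'   shaded and the 3x-SD distinctness threshold marked.
#' @param object A `distance_trace`.
#' @param ... Unused.
#' @method autoplot distance_trace
#' @export
autoplot.distance_trace <- function(object, ...) {
  df <- as_tibble(object)
  onset <- object$odor_onset_frame * object$frame_period
  offset <- onset + object$odor_duration_frames * object$frame_period
  thr <- object$baseline_mean + 3 * object$baseline_sd
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$d)) +
    ggplot2::annotate("rect", xmin = onset, xmax = offset, ymin = -Inf,
                      ymax = Inf, alpha = 0.15) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "Euclidean distance",
                  title = sprintf("%s vs %s", object$stimuli[1], object$stimuli[2]),
                  subtitle = "dashed: baseline mean + 3 SD") +
    ggplot2::theme_minimal()
}

#' @describeIn glom_traces Plot all glomerular time courses with the odor
#'   window shaded.
#' @param object A `glom_traces`.
#' @param ... Unused.
#' @method autoplot glom_traces
#' @export
autoplot.glom_traces <- function(object, ...) {
  df <- as_tibble(object)
  onset <- object$odor_onset_frame * object$frame_period
  offset <- onset + object$odor_duration_frames * object$frame_period
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   group = .data$glomerulus,
                                   colour = factor(.data$glomerulus))) +
    ggplot2::annotate("rect", xmin = onset, xmax = offset, ymin = -Inf,
                      ymax = Inf, alpha = 0.15) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::labs(x = "time (s)", y = expression(Delta * R),
                  title = sprintf("stimulus '%s'", object$stimulus)) +
    ggplot2::theme_minimal()
}

#' @describeIn run_report Effect-size overview of a cohort report: one point
#'   per comparison, filled by significance.
#' @param object A `cohort_report`.
#' @param ... Unused.
#' @method autoplot cohort_report
#' @export
autoplot.cohort_report <- function(object, ...) {
  df <- object$results
  df <- df[!is.na(df$effect_size_d), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect_size_d,
                                   y = stats::reorder(.data$id, .data$effect_size_d),
                                   colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Cohen's d (solvent - inhibitor)", y = NULL,
                  colour = sprintf("p < %g", object$alpha)) +
    ggplot2::theme_minimal()
}

#' Plot M17 memory scores
#'
#' Mean +/- SEM of the baseline-normalized M17 rate per stimulus, faceted by
#' training group, coloured by treatment.
#'
#' @param scores Tibble from [memory_scores()].
#' @return A ggplot object.
#' @export
plot_memory_scores <- function(scores) {
  scores$stimulus <- factor(scores$stimulus, levels = stimulus_labels())
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$stimulus, y = .data$mean,
                                       fill = .data$treatment)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.25) +
    ggplot2::facet_wrap(~ .data$group) +
    ggplot2::labs(x = NULL, y = "normalized rate (Hz)") +
    ggplot2::theme_minimal()
}
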