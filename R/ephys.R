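#' M17 spike record
#'
#' Spike times (seconds from trial start) from the proboscis-extension muscle
#' M17, with the standard windows: a 5 s pre-stimulus baseline immediately
#' followed by the 4 s odor stimulus.
#'
#' @param spike_times Numeric vector of spike times in seconds (sorted
#'   internally).
#' @param baseline_window,odor_window Two-element `c(start, end)` vectors in
#'   seconds; must not overlap.
#' @param stimulus Stimulus label.
#' @param bee,group,treatment Cohort annotations.
#' @param trial_end End of the trial in seconds (default: odor window end);
#'   spikes outside `[0, trial_end]` are rejected.
#' @return An object of class `m17_record`.
#' @export
m17_record <- function(spike_times, baseline_window = c(0, 5),
                       odor_window = c(5, 9), stimulus = "csplus",
                       bee = NA_character_, group = NA_character_,
                       treatment = NA_character_, trial_end = NULL) {
  spike_times <- sort(as.numeric(spike_times))
  trial_end <- trial_end %||% max(odor_window)
  if (length(baseline_window) != 2L || length(odor_window) != 2L ||
      diff(baseline_window) <= 0 || diff(odor_window) <= 0) {
    stop_glomsep("windows must be increasing c(start, end) pairs")
  }
  if (max(baseline_window[1], odor_window[1]) < min(baseline_window[2], odor_window[2])) {
    stop_glomsep("baseline and odor windows must not overlap")
  }
  if (length(spike_times) && (min(spike_times) < 0 || max(spike_times) > trial_end)) {
    stop_glomsep("spike times outside trial bounds [0, %s] s", format(trial_end))
  }
  stimulus <- match.arg(stimulus, stimulus_labels())
  structure(list(spike_times = spike_times, baseline_window = baseline_window,
                 odor_window = odor_window, stimulus = stimulus, bee = bee,
                 group = group, treatment = treatment, trial_end = trial_end),
            class = "m17_record")
}

#' @export
print.m17_record <- function(x, ...) {
  cat(sprintf("<m17_record> %d spikes, baseline %g-%g s, odor %g-%g s, stimulus '%s'\n",
              length(x$spike_times), x$baseline_window[1], x$baseline_window[2],
              x$odor_window[1], x$odor_window[2], x$stimulus))
  invisible(x)
}

#' Baseline-normalized M17 response rate
#'
#' The odor-window spike frequency normalized by the immediately preceding
#' baseline frequency. The default normalization is subtractive —
#' `odor_rate - baseline_rate` in Hz, negative values indicating suppression —
#' because near-zero baseline rates (mineral oil, ~1 Hz) make ratios
#' unstable; divisive normalization is available via `mode = "divide"`
#' (returns `NA` with a warning when the baseline is silent).
#'
#' @param rec An [m17_record()].
#' @param mode `"subtract"` (default) or `"divide"`.
#' @return Scalar rate (Hz for `"subtract"`, dimensionless for `"divide"`).
#' @export
normalized_rate <- function(rec, mode = c("subtract", "divide")) {
  stopifnot(inherits(rec, "m17_record"))
  mode <- match.arg(mode)
  in_win <- function(w) sum(rec$spike_times >= w[1] & rec$spike_times < w[2])
  odor <- in_win(rec$odor_window) / diff(rec$odor_window)
  base <- in_win(rec$baseline_window) / diff(rec$baseline_window)
  if (mode == "subtract") return(odor - base)
  if (base == 0) {
    warn("baseline window has no spikes: divisive normalization undefined")
    return(NA_real_)
  }
  odor / base
}

# Tabular spikes (bee, group, treatment, stimulus, spike_time; NA = no
# spikes) -> list of m17_record.
records_from_spike_table <- function(df, baseline_window = c(0, 5),
                                     odor_window = c(5, 9)) {
  need <- c("bee", "group", "treatment", "stimulus", "spike_time")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_glomsep("spike table is missing columns: %s", paste(miss, collapse = ", "))
  key <- paste(df$bee, df$stimulus, sep = "\r")
  lapply(split(df, key), function(d) {
    st <- d$spike_time[!is.na(d$spike_time)]
    m17_record(st, baseline_window, odor_window, stimulus = d$stimulus[1],
               bee = d$bee[1], group = d$group[1], treatment = d$treatment[1])
  })
}

#' Per-bee M17 response rates from a tabular spike cohort
#'
#' @param df Long spike table (`bee, group, treatment, stimulus, spike_time`;
#'   `NA` spike time marks a trial with no spikes).
#' @param mode Normalization mode, see [normalized_rate()].
#' @param baseline_window,odor_window Trial windows in seconds.
#' @return Tibble `bee, group, treatment, stimulus, rate`.
#' @export
m17_rates <- function(df, mode = c("subtract", "divide"),
                      baseline_window = c(0, 5), odor_window = c(5, 9)) {
  mode <- match.arg(mode)
  recs <- records_from_spike_table(df, baseline_window, odor_window)
  dplyr::arrange(dplyr::bind_rows(lapply(recs, function(r) {
    tibble(bee = r$bee, group = r$group, treatment = r$treatment,
           stimulus = r$stimulus, rate = normalized_rate(r, mode))
  })), .data$group, .data$treatment, .data$bee, .data$stimulus)
}

#' Cohort summary of M17 memory scores
#'
#' Mean, SEM and n of the baseline-normalized response rate per
#' group x treatment x stimulus. Bees missing a stimulus are simply absent
#' from that cell (reported via a message).
#'
#' @inheritParams m17_rates
#' @return Tibble `group, treatment, stimulus, n, mean, sem`.
#' @export
memory_scores <- function(df, mode = c("subtract", "divide"),
                          baseline_window = c(0, 5), odor_window = c(5, 9)) {
  rates <- m17_rates(df, mode, baseline_window, odor_window)
  n_stim <- length(unique(rates$stimulus))
  incomplete <- dplyr::filter(dplyr::count(rates, .data$bee), .data$n < n_stim)
  if (nrow(incomplete)) {
    inform(sprintf("%d bee(s) missing stimuli; excluded from affected cells",
                   nrow(incomplete)))
  }
  out <- dplyr::summarise(
    dplyr::group_by(rates, .data$group, .data$treatment, .data$stimulus),
    n = dplyr::n(),
    mean = mean(.data$rate),
    sem = if (dplyr::n() > 1) sd(.data$rate) / sqrt(dplyr::n()) else NA_real_,
    .groups = "drop")
  dplyr::arrange(out, .data$group, .data$treatment,
                 match(.data$stimulus, stimulus_labels()))
}
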