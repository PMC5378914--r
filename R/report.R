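#' Default cohort comparison manifest
#'
#' The comparison set the analysis runs by default, mirroring the study
#' design. Treatment contrasts (solvent vs inhibitor, independent samples)
#' are run within each training group for: early-window and whole-odor
#' CS+/new separation, the distinct-pattern proportion, percent responders to
#' the new odor, dominant-glomeruli peak responses, per-trial extinction
#' distances and dominant-glomeruli extinction peaks, the M17 new-odor
#' response and the last extinction trial. Within-bee paired contrasts
#' compare the M17 CS+ response against mineral oil per cell (one-tailed:
#' conditioned responding predicts CS+ > oil). The early-window separation
#' contrast in the paired group is one-tailed (solvent > inhibitor), encoding
#' the directional prior that Dnmt inhibition slows pattern separation; all
#' other contrasts are two-tailed.
#'
#' @return A tibble, one row per comparison (columns: `id, source, metric,
#'   stimulus, group, treatment, comparison, ref_stimulus, design, tails,
#'   direction`).
#' @export
default_manifest <- function() {
  tc <- function(id, metric, stimulus, group, tails = "two", direction = NA_character_,
                 source = "metrics") {
    tibble(id = id, source = source, metric = metric, stimulus = stimulus,
           group = group, treatment = NA_character_, comparison = "treatment",
           ref_stimulus = NA_character_, design = "independent",
           tails = tails, direction = direction)
  }
  wb <- function(id, stimulus, ref, group, treatment, tails = "one",
                 direction = "greater") {
    tibble(id = id, source = "ephys", metric = "rate", stimulus = stimulus,
           group = group, treatment = treatment, comparison = "stimulus_within_bee",
           ref_stimulus = ref, design = "paired", tails = tails,
           direction = direction)
  }
  rows <- list(
    tc("early_separation_paired", "early_separation", "new", "paired",
       tails = "one", direction = "greater"),
    tc("early_separation_unpaired", "early_separation", "new", "unpaired"),
    tc("odor_separation_paired", "odor_separation", "new", "paired"),
    tc("odor_separation_unpaired", "odor_separation", "new", "unpaired"),
    tc("distinct_paired", "distinct", "new", "paired",
       tails = "one", direction = "greater"),
    tc("distinct_unpaired", "distinct", "new", "unpaired"),
    tc("responders_new_paired", "pct_responders", "new", "paired"),
    tc("responders_new_unpaired", "pct_responders", "new", "unpaired"),
    tc("dominant_new_paired", "dominant_peak_ref_new", "new", "paired"),
    tc("dominant_new_unpaired", "dominant_peak_ref_new", "new", "unpaired"),
    tc("dominant_csplus_paired", "dominant_peak_ref_csplus", "csplus", "paired"),
    tc("dominant_csplus_unpaired", "dominant_peak_ref_csplus", "csplus", "unpaired"))
  for (g in c("paired", "unpaired")) {
    for (j in 2:6) {
      rows[[length(rows) + 1L]] <- tc(
        sprintf("extinction_distance_%s_ext%d", g, j),
        "extinction_distance", paste0("ext", j), g)
    }
    for (j in 1:6) {
      rows[[length(rows) + 1L]] <- tc(
        sprintf("extinction_dominant_%s_ext%d", g, j),
        "dominant_peak_ref_ext1", paste0("ext", j), g)
    }
  }
  for (g in c("paired", "unpaired")) for (tr in c("solvent", "inhibitor")) {
    rows[[length(rows) + 1L]] <- wb(
      sprintf("m17_csplus_vs_oil_%s_%s", g, tr), "csplus", "oil", g, tr)
  }
  rows[[length(rows) + 1L]] <- tc("m17_new_paired", "rate", "new", "paired",
                                  source = "ephys")
  rows[[length(rows) + 1L]] <- tc("m17_new_unpaired", "rate", "new", "unpaired",
                                  source = "ephys")
  rows[[length(rows) + 1L]] <- tc("m17_ext6_paired", "rate", "ext6", "paired",
                                  source = "ephys")
  dplyr::bind_rows(rows)
}

#' Read/write a comparison manifest as YAML
#' @param manifest Manifest tibble (see [default_manifest()]).
#' @param path YAML file path.
#' @export
write_manifest_yaml <- function(manifest, path) {
  yaml::write_yaml(lapply(seq_len(nrow(manifest)), function(i) {
    as.list(manifest[i, ])
  }), path)
  invisible(path)
}

#' @rdname write_manifest_yaml
#' @export
read_manifest_yaml <- function(path) {
  rows <- yaml::read_yaml(path)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble(id = r$id, source = r$source, metric = r$metric,
           stimulus = r$stimulus, group = r$group %||% NA_character_,
           treatment = r$treatment %||% NA_character_,
           comparison = r$comparison,
           ref_stimulus = r$ref_stimulus %||% NA_character_,
           design = r$design, tails = r$tails,
           direction = r$direction %||% NA_character_)
  }))
}

#' Run the cohort comparison manifest
#'
#' Executes every comparison in the manifest over the per-bee metrics table
#' and (optionally) the per-bee M17 rate table, using the normality-gated
#' test-selection workflow of [compare_groups()]. Treatment contrasts pull
#' solvent (x) vs inhibitor (y) samples within a training group; within-bee
#' contrasts pair each bee's response to a stimulus with its response to the
#' reference stimulus (bees missing either are dropped). No multiple-testing
#' correction is applied; the number of comparisons is reported so users can
#' apply their own.
#'
#' @param metrics Tibble from [cohort_metrics()].
#' @param ephys Optional tibble from [m17_rates()].
#' @param manifest Comparison manifest (default [default_manifest()]);
#'   rows referencing metrics absent from the tables cause an error listing
#'   every gap.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `cohort_report`: a results tibble (one row per
#'   comparison, including diagnostics and any warnings raised) plus `alpha`
#'   and `n_comparisons`.
#' @export
run_report <- function(metrics, ephys = NULL, manifest = default_manifest(),
                       alpha = 0.05) {
  if (nrow(manifest) == 0L) {
    return(structure(list(results = tibble(), alpha = alpha, n_comparisons = 0L),
                     class = "cohort_report"))
  }
  get_samples <- function(row) {
    src <- if (row$source == "metrics") metrics else ephys
    if (is.null(src)) return(NULL)
    if (row$source == "metrics") {
      sub <- src[src$metric == row$metric & src$stimulus == row$stimulus &
                   src$group == row$group, ]
      if (!nrow(sub)) return(NULL)
      list(x = sub$value[sub$treatment == "solvent"],
           y = sub$value[sub$treatment == "inhibitor"])
    } else if (row$comparison == "treatment") {
      sub <- src[src$stimulus == row$stimulus & src$group == row$group, ]
      if (!nrow(sub)) return(NULL)
      list(x = sub$rate[sub$treatment == "solvent"],
           y = sub$rate[sub$treatment == "inhibitor"])
    } else {
      sub <- src[src$group == row$group & src$treatment == row$treatment, ]
      a <- sub[sub$stimulus == row$stimulus, c("bee", "rate")]
      b <- sub[sub$stimulus == row$ref_stimulus, c("bee", "rate")]
      m <- merge(a, b, by = "bee")
      if (!nrow(m)) return(NULL)
      list(x = m$rate.x, y = m$rate.y)
    }
  }
  samples <- lapply(seq_len(nrow(manifest)), function(i) get_samples(manifest[i, ]))
  gaps <- manifest$id[vapply(samples, is.null, TRUE)]
  if (length(gaps)) {
    stop_glomsep("manifest references data absent from the input tables: %s",
                 paste(gaps, collapse = ", "))
  }
  res <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    s <- samples[[i]]
    notes <- character(0)
    ct <- withCallingHandlers(
      compare_groups(s$x, s$y, design = row$design, tails = row$tails,
                     direction = if (is.na(row$direction)) NULL else row$direction,
                     alpha = alpha),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    dplyr::bind_cols(
      row[c("id", "source", "metric", "stimulus", "group", "treatment", "comparison")],
      tidy(ct),
      tibble(note = if (length(notes)) paste(unique(notes), collapse = "; ") else ""))
  })
  structure(list(results = dplyr::bind_rows(res), alpha = alpha,
                 n_comparisons = nrow(manifest)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d comparisons at alpha = %g, %d significant (uncorrected)\n",
              x$n_comparisons, x$alpha,
              if (nrow(x$results)) sum(x$results$significant) else 0L))
  if (nrow(x$results)) {
    sig <- x$results[x$results$significant, c("id", "test_used", "p_value", "effect_size_d")]
    if (nrow(sig)) print(sig, n = 20)
  }
  invisible(x)
}

#' @method tidy cohort_report
#' @export
tidy.cohort_report <- function(x, ...) x$results

#' Write a cohort report to JSON (and optionally Markdown)
#'
#' @param report A `cohort_report`.
#' @param json_path Output JSON path.
#' @param md_path Optional Markdown summary path.
#' @export
write_report <- function(report, json_path, md_path = NULL) {
  stopifnot(inherits(report, "cohort_report"))
  payload <- list(alpha = report$alpha, n_comparisons = report$n_comparisons,
                  results = report$results)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(md_path)) {
    r <- report$results
    lines <- c("# Cohort comparison report", "",
               sprintf("%d comparisons at alpha = %g (uncorrected).",
                       report$n_comparisons, report$alpha), "",
               "| id | test | p | d | category | n | sig |",
               "|---|---|---|---|---|---|---|",
               vapply(seq_len(nrow(r)), function(i) {
                 sprintf("| %s | %s | %.4g | %s | %s | %d/%d | %s |",
                         r$id[i], r$test_used[i], r$p_value[i],
                         ifelse(is.na(r$effect_size_d[i]), "-",
                                sprintf("%.3f", r$effect_size_d[i])),
                         ifelse(is.na(r$effect_category[i]), "-", r$effect_category[i]),
                         r$n1[i], r$n2[i],
                         ifelse(r$significant[i], "*", ""))
               }, character(1)))
    writeLines(lines, md_path)
  }
  invisible(json_path)
}
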