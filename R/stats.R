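#' Cohen's d with pooled standard deviation
#'
#' `d = (mean(x) - mean(y)) / s_pooled`, with
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @return Scalar effect size (sign: positive when `mean(x) > mean(y)`).
#' @seealso [effect_category()]
#' @export
cohens_d <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop_glomsep("each sample needs n >= 2")
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  if (sp == 0) stop_glomsep("pooled SD is zero: effect size undefined")
  (mean(x) - mean(y)) / sp
}

#' Effect-size category
#'
#' The conventional |d| bands: below 0.2 negligible, 0.2--0.5 small,
#' 0.5--0.8 medium, above 0.8 large.
#'
#' @param d Cohen's d (scalar or vector; `NA` passes through).
#' @return Character vector of categories.
#' @export
effect_category <- function(d) {
  out <- rep(NA_character_, length(d))
  a <- abs(d)
  out[!is.na(a) & a < 0.2] <- "negligible"
  out[!is.na(a) & a >= 0.2 & a < 0.5] <- "small"
  out[!is.na(a) & a >= 0.5 & a < 0.8] <- "medium"
  out[!is.na(a) & a >= 0.8] <- "large"
  out
}

#' Normality-gated two-sample comparison
#'
#' The test-selection workflow: both samples are tested for normality
#' (Shapiro-Wilk; for paired designs the differences are tested) and, for
#' independent designs, for equal variance (F-test). If every diagnostic
#' p-value exceeds 0.05 a Student's t-test is used (pooled-variance for
#' independent, paired otherwise); otherwise the non-parametric counterpart:
#' Mann-Whitney U for independent samples, Wilcoxon signed-rank for paired.
#' Constant samples or n < 3 fall back to the non-parametric path with a
#' warning (Shapiro-Wilk is undefined there). One-tailed tests require a
#' stated direction. Rank tests use the exact distribution for n <= 25
#' without ties, else the tie-corrected normal approximation with continuity
#' correction.
#'
#' @param x,y Numeric samples. `direction = "greater"` means the alternative
#'   `x > y`.
#' @param design `"independent"` or `"paired"` (paired requires equal
#'   lengths).
#' @param tails `"two"` (default) or `"one"`.
#' @param direction Required for one-tailed tests: `"greater"` or `"less"`.
#' @param alpha Significance level used for the `significant` flag and
#'   reported in the result (default 0.05). The diagnostic gates are fixed at
#'   p > 0.05.
#' @return An object of class `cohort_test`; see [tidy.cohort_test()].
#' @export
compare_groups <- function(x, y, design = c("independent", "paired"),
                           tails = c("two", "one"), direction = NULL,
                           alpha = 0.05) {
  design <- match.arg(design)
  tails <- match.arg(tails)
  if (!length(x) || !length(y)) stop_glomsep("empty sample")
  if (design == "paired" && length(x) != length(y)) {
    stop_glomsep("paired design requires equal sample sizes")
  }
  if (tails == "one") {
    if (is.null(direction)) stop_glomsep("one-tailed tests require a direction")
    direction <- match.arg(direction, c("greater", "less"))
  } else {
    direction <- NA_character_
  }
  alternative <- if (tails == "two") "two.sided" else direction

  sw <- function(v) {
    if (length(v) < 3L || length(v) > 5000L || sd(v) == 0) return(NA_real_)
    shapiro.test(v)$p.value
  }
  if (design == "independent") {
    p_norm <- c(sw(x), sw(y))
    p_var <- if (sd(x) > 0 && sd(y) > 0) var.test(x, y)$p.value else NA_real_
  } else {
    p_norm <- c(sw(x - y), NA_real_)
    p_var <- NA_real_
  }
  diag_ok <- if (design == "independent") {
    !anyNA(p_norm) && !is.na(p_var) && all(p_norm > 0.05) && p_var > 0.05
  } else {
    !is.na(p_norm[1]) && p_norm[1] > 0.05
  }
  if ((design == "independent" && (anyNA(p_norm) || is.na(p_var))) ||
      (design == "paired" && is.na(p_norm[1]))) {
    warn("normality/variance diagnostics unavailable (small or constant sample); using the non-parametric test")
  }

  if (diag_ok) {
    ht <- t.test(x, y, alternative = alternative, paired = design == "paired",
                 var.equal = TRUE)
    test_used <- if (design == "paired") "paired t" else "t"
  } else {
    exact <- max(length(x), length(y)) <= 25 &&
      !any(duplicated(if (design == "paired") abs(x - y) else c(x, y)))
    ht <- suppressWarnings(
      wilcox.test(x, y, alternative = alternative, paired = design == "paired",
                  exact = exact, correct = !exact))
    test_used <- if (design == "paired") "wilcoxon" else "mann-whitney"
  }
  d <- tryCatch(cohens_d(x, y), glomsep_error = function(e) NA_real_)

  structure(list(
    test_used = test_used, p_value = ht$p.value, statistic = unname(ht$statistic),
    effect_size_d = d, effect_category = effect_category(d),
    n = c(length(x), length(y)), design = design, tails = tails,
    direction = direction, alpha = alpha, significant = ht$p.value < alpha,
    diagnostics = list(shapiro_p = p_norm, var_p = p_var, gate_passed = diag_ok)),
    class = "cohort_test")
}

#' @export
print.cohort_test <- function(x, ...) {
  cat(sprintf("<cohort_test> %s (%s, %s-tailed): p = %.4g, d = %.3f (%s), n = %d/%d\n",
              x$test_used, x$design, x$tails, x$p_value,
              x$effect_size_d, x$effect_category, x$n[1], x$n[2]))
  invisible(x)
}

#' Tidy a cohort comparison
#'
#' @param x A `cohort_test`.
#' @param ... Unused.
#' @return One-row tibble with the test used, p-value, effect size and
#'   category, sample sizes, and diagnostic p-values.
#' @method tidy cohort_test
#' @export
tidy.cohort_test <- function(x, ...) {
  tibble(test_used = x$test_used, p_value = x$p_value,
         effect_size_d = x$effect_size_d, effect_category = x$effect_category,
         n1 = x$n[1], n2 = x$n[2], design = x$design, tails = x$tails,
         direction = x$direction, significant = x$significant,
         shapiro_p1 = x$diagnostics$shapiro_p[1],
         shapiro_p2 = x$diagnostics$shapiro_p[2],
         var_p = x$diagnostics$var_p)
}

#' @rdname tidy.cohort_test
#' @method glance cohort_test
#' @export
glance.cohort_test <- function(x, ...) {
  tibble(test_used = x$test_used, p_value = x$p_value,
         effect_size_d = x$effect_size_d, significant = x$significant)
}

#' Fisher's exact test on an exclusion table
#'
#' Two-sided exact p-value for a 2x2 contingency table (e.g. excluded vs kept
#' bees by treatment), by summing the hypergeometric probabilities of all
#' tables at most as probable as the observed one. A zero margin yields
#' p = 1 with a warning.
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @return A `cohort_test` with `test_used = "fisher"` (no effect size).
#' @export
fisher_exclusion <- function(counts) {
  counts <- as.matrix(counts)
  if (!identical(dim(counts), c(2L, 2L)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop_glomsep("`counts` must be a 2x2 matrix of non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    warn("zero margin: Fisher's exact test degenerate, p = 1")
    p <- 1
  } else {
    p <- fisher.test(counts)$p.value
  }
  structure(list(
    test_used = "fisher", p_value = p, statistic = NA_real_,
    effect_size_d = NA_real_, effect_category = NA_character_,
    n = c(sum(counts[1, ]), sum(counts[2, ])), design = "independent",
    tails = "two", direction = NA_character_, alpha = 0.05,
    significant = p < 0.05,
    diagnostics = list(shapiro_p = c(NA_real_, NA_real_), var_p = NA_real_,
                       gate_passed = NA)),
    class = "cohort_test")
}
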