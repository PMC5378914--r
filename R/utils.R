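# Internal helpers shared across modules.

# Deterministic seed derivation: one stream per (master seed, index...) so
# individual bees/stimuli can be regenerated without replaying the whole
# cohort. Kept below 2^31 - 1; arithmetic stays within double precision.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.numeric(master) %% 1000003
  for (i in idx) {
    s <- (s * 69069 + as.numeric(i) + 1) %% 2147483647
  }
  as.integer(s) + 1L
}

stop_glomsep <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "glomsep_error")
}

check_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_glomsep("`%s` must be a single finite number", name)
  }
  if (strict_min && x <= min) stop_glomsep("`%s` must be > %s", name, min)
  if (!strict_min && x < min) stop_glomsep("`%s` must be >= %s", name, min)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar_number(x, name, min = min)
  if (x != round(x)) stop_glomsep("`%s` must be an integer count", name)
  invisible(as.integer(x))
}

# Expand a scalar or partially named per-cell value to the four
# (group x treatment) cells used throughout.
cell_names <- function() {
  c("paired_solvent", "paired_inhibitor", "unpaired_solvent", "unpaired_inhibitor")
}

cell_key <- function(group, treatment) {
  group <- match.arg(group, c("paired", "unpaired"))
  treatment <- match.arg(treatment, c("solvent", "inhibitor"))
  paste(group, treatment, sep = "_")
}

expand_cells <- function(x, name) {
  cells <- cell_names()
  if (length(x) == 1L && is.null(names(x))) {
    out <- rep(as.numeric(x), 4L)
    names(out) <- cells
    return(out)
  }
  if (is.null(names(x)) && length(x) == 4L) {
    out <- as.numeric(x)
    names(out) <- cells
    return(out)
  }
  if (!all(names(x) %in% cells)) {
    stop_glomsep("`%s` names must be among: %s", name, paste(cells, collapse = ", "))
  }
  out <- stats::setNames(rep(NA_real_, 4L), cells)
  out[names(x)] <- as.numeric(x)
  if (anyNA(out)) stop_glomsep("`%s` must cover all four group x treatment cells", name)
  out
}
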