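#' Dual-wavelength movie container
#'
#' Holds a FURA-2 recording: two fluorescence stacks (340 nm and 380 nm
#' excitation) as `H x W x n_frames` arrays plus the stimulus timing metadata
#' needed downstream. Ratios are always computed as F340/F380, so F380 must be
#' strictly positive everywhere.
#'
#' @param f340,f380 Numeric arrays `H x W x n_frames` of non-negative
#'   intensities (same shape).
#' @param frame_period Frame duration in seconds (80 ms at 12.5 Hz double
#'   frames).
#' @param odor_onset_frame 0-based index of the first odor frame.
#' @param odor_duration_frames Number of odor frames.
#' @param stimulus Stimulus label, one of [stimulus_labels()].
#' @return An object of class `dual_movie`.
#' @export
dual_movie <- function(f340, f380, frame_period, odor_onset_frame,
                       odor_duration_frames, stimulus = "csplus") {
  if (!is.array(f340) || length(dim(f340)) != 3L) stop_glomsep("`f340` must be an H x W x T array")
  if (!identical(dim(f340), dim(f380))) stop_glomsep("`f340` and `f380` must have the same shape")
  if (any(f340 < 0) || any(f380 < 0)) stop_glomsep("fluorescence intensities must be non-negative")
  check_scalar_number(frame_period, "frame_period", min = 0, strict_min = TRUE)
  n_frames <- dim(f340)[3]
  odor_onset_frame <- check_count(odor_onset_frame, "odor_onset_frame", min = 0L)
  odor_duration_frames <- check_count(odor_duration_frames, "odor_duration_frames")
  if (odor_onset_frame >= n_frames) stop_glomsep("`odor_onset_frame` beyond recording")
  stimulus <- match.arg(stimulus, stimulus_labels())
  structure(
    list(f340 = f340, f380 = f380, frame_period = frame_period,
         odor_onset_frame = odor_onset_frame,
         odor_duration_frames = odor_duration_frames,
         stimulus = stimulus),
    class = "dual_movie")
}

#' Stimulus labels used throughout the package
#'
#' The recording protocol: trained odor (`csplus`), a new odor (`new`), the
#' odor solvent mineral oil (`oil`), the binary mixture (`mix`), and six
#' unreinforced CS+ extinction trials (`ext1`..`ext6`).
#' @return Character vector of the ten labels.
#' @export
stimulus_labels <- function() {
  c("csplus", "new", "oil", "mix", paste0("ext", 1:6))
}

#' @export
print.dual_movie <- function(x, ...) {
  d <- dim(x$f340)
  cat(sprintf("<dual_movie> %d x %d px, %d frames @ %.0f ms, stimulus '%s', odor frames %d..%d\n",
              d[1], d[2], d[3], x$frame_period * 1000, x$stimulus,
              x$odor_onset_frame, x$odor_onset_frame + x$odor_duration_frames - 1L))
  invisible(x)
}

# Baseline-subtracted ratio movie (internal constructor; use compute_ratio()).
new_ratio_movie <- function(delta_r, baseline_frames, frame_period,
                            odor_onset_frame, odor_duration_frames, stimulus) {
  structure(
    list(delta_r = delta_r, baseline_frames = baseline_frames,
         frame_period = frame_period, odor_onset_frame = odor_onset_frame,
         odor_duration_frames = odor_duration_frames, stimulus = stimulus),
    class = "ratio_movie")
}

#' @export
print.ratio_movie <- function(x, ...) {
  d <- dim(x$delta_r)
  cat(sprintf("<ratio_movie> %d x %d px, %d frames, baseline frames %d..%d, stimulus '%s'\n",
              d[1], d[2], d[3], min(x$baseline_frames), max(x$baseline_frames), x$stimulus))
  invisible(x)
}

# ---- TIFF + JSON sidecar IO ------------------------------------------------
# Float TIFF samples are stored scaled into [0, 1]; the scale factor lives in
# the sidecar so values round-trip at float32 precision.

write_stack_tiff <- function(arr, path, scale) {
  pages <- lapply(seq_len(dim(arr)[3]), function(i) arr[, , i] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

read_stack_tiff <- function(path, scale) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]] * scale
  arr
}

#' Write/read a dual-wavelength movie as multi-page TIFF plus JSON sidecar
#'
#' Files written: `<prefix>_340.tif`, `<prefix>_380.tif`, `<prefix>.json`.
#' Intensities are scaled into `[0, 1]` for float TIFF storage; the scale is
#' recorded in the sidecar and re-applied on read.
#'
#' @param movie A [dual_movie()].
#' @param dir Output directory.
#' @param prefix File name prefix (e.g. `"bee01_csplus"`).
#' @return `write_movie()`: the prefix path, invisibly. `read_movie()`: a
#'   [dual_movie()].
#' @export
write_movie <- function(movie, dir, prefix) {
  stopifnot(inherits(movie, "dual_movie"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scale <- max(movie$f340, movie$f380, 1)
  base <- file.path(dir, prefix)
  write_stack_tiff(movie$f340, paste0(base, "_340.tif"), scale)
  write_stack_tiff(movie$f380, paste0(base, "_380.tif"), scale)
  meta <- list(frame_period = movie$frame_period,
               odor_onset_frame = movie$odor_onset_frame,
               odor_duration_frames = movie$odor_duration_frames,
               stimulus = movie$stimulus,
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' @rdname write_movie
#' @param prefix_path Path prefix as returned by `write_movie()`.
#' @export
read_movie <- function(prefix_path) {
  meta <- jsonlite::read_json(paste0(prefix_path, ".json"), simplifyVector = TRUE)
  f340 <- read_stack_tiff(paste0(prefix_path, "_340.tif"), meta$intensity_scale)
  f380 <- read_stack_tiff(paste0(prefix_path, "_380.tif"), meta$intensity_scale)
  dual_movie(f340, f380, meta$frame_period, meta$odor_onset_frame,
             meta$odor_duration_frames, meta$stimulus)
}

#' Write/read a glomerulus label image as TIFF
#'
#' Labels (0 = background, k = glomerulus k) are stored as uint16.
#' @param labels Integer label matrix.
#' @param path Output `.tif` path.
#' @export
write_label_tiff <- function(labels, path) {
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  round(tiff::readTIFF(path) * 65535)
}
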