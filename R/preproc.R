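# Movement correction and ratiometric normalization.

# Circular (wrap-around) integer translation: content moves +dy rows, +dx cols.
shift_matrix <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- ((seq_len(nr) - 1 - dy) %% nr) + 1
  ci <- ((seq_len(nc) - 1 - dx) %% nc) + 1
  m[ri, ci, drop = FALSE]
}

# Bilinear circular translation for subpixel shifts.
shift_matrix_subpixel <- function(m, dy, dx) {
  fy <- floor(dy); fx <- floor(dx)
  ay <- dy - fy; ax <- dx - fx
  m00 <- shift_matrix(m, fy, fx)
  if (ay == 0 && ax == 0) return(m00)
  m10 <- shift_matrix(m, fy + 1, fx)
  m01 <- shift_matrix(m, fy, fx + 1)
  m11 <- shift_matrix(m, fy + 1, fx + 1)
  (1 - ay) * (1 - ax) * m00 + ay * (1 - ax) * m10 +
    (1 - ay) * ax * m01 + ay * ax * m11
}

# Phase cross-correlation: returns the translation (dy, dx) by which `frame`
# is displaced relative to `ref` (circular model). Subpixel refinement by a
# 1D parabolic fit through the correlation peak in each axis.
phase_shift <- function(frame, ref, subpixel = FALSE) {
  if (sd(frame) == 0 || sd(ref) == 0) {
    warn("constant frame: cross-correlation undefined, assuming zero shift")
    return(c(0, 0))
  }
  fa <- fft(frame); fb <- fft(ref)
  cp <- fa * Conj(fb)
  cp <- cp / (Mod(cp) + 1e-12)
  corr <- Re(fft(cp, inverse = TRUE))
  peak <- arrayInd(which.max(corr), dim(corr))
  nr <- nrow(corr); nc <- ncol(corr)
  dy <- peak[1] - 1; dx <- peak[2] - 1
  if (subpixel) {
    py <- c(corr[(peak[1] - 2) %% nr + 1, peak[2]], corr[peak[1], peak[2]],
            corr[peak[1] %% nr + 1, peak[2]])
    px <- c(corr[peak[1], (peak[2] - 2) %% nc + 1], corr[peak[1], peak[2]],
            corr[peak[1], peak[2] %% nc + 1])
    dy <- dy + parabolic_offset(py)
    dx <- dx + parabolic_offset(px)
  }
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  c(dy, dx)
}

parabolic_offset <- function(p) {
  den <- p[1] - 2 * p[2] + p[3]
  if (den == 0) return(0)
  off <- 0.5 * (p[1] - p[3]) / den
  max(min(off, 0.5), -0.5)
}

#' Rigid movement correction within a movie
#'
#' Estimates, per frame, the rigid translation relative to a reference frame
#' by FFT phase cross-correlation (on the mean of the two wavelength channels)
#' and applies the corrective shift to both channels identically. The default
#' reference is the middle frame of the pre-odor baseline. Registering an
#' already-registered movie yields all-zero shifts.
#'
#' @param movie A [dual_movie()].
#' @param reference_frame 0-based reference frame index; default: middle of
#'   the pre-onset period.
#' @param subpixel Logical; refine shifts to subpixel accuracy (parabolic peak
#'   interpolation, bilinear resampling). Default `FALSE` (integer pixels).
#' @return A list with `movie` (the registered [dual_movie()]) and `shifts`, a
#'   tibble with columns `frame` (0-based), `dy`, `dx` — the applied
#'   corrective shifts (a frame drifted by `(+2, 0)` gets shift `(-2, 0)`).
#' @export
register_movie <- function(movie, reference_frame = NULL, subpixel = FALSE) {
  stopifnot(inherits(movie, "dual_movie"))
  n <- dim(movie$f340)[3]
  if (is.null(reference_frame)) reference_frame <- max(0L, floor(movie$odor_onset_frame / 2))
  reference_frame <- check_count(reference_frame, "reference_frame", min = 0L)
  if (reference_frame >= n) stop_glomsep("`reference_frame` beyond recording")
  ref <- (movie$f340[, , reference_frame + 1L] + movie$f380[, , reference_frame + 1L]) / 2
  shifts <- matrix(0, n, 2)
  f340 <- movie$f340; f380 <- movie$f380
  shift_fun <- if (subpixel) shift_matrix_subpixel else shift_matrix
  for (i in seq_len(n)) {
    fr <- (movie$f340[, , i] + movie$f380[, , i]) / 2
    s <- phase_shift(fr, ref, subpixel = subpixel)
    corr <- -s
    shifts[i, ] <- corr
    if (any(corr != 0)) {
      f340[, , i] <- shift_fun(movie$f340[, , i], corr[1], corr[2])
      f380[, , i] <- shift_fun(movie$f380[, , i], corr[1], corr[2])
    }
  }
  out <- movie
  out$f340 <- f340; out$f380 <- f380
  list(movie = out,
       shifts = tibble(frame = seq_len(n) - 1L, dy = shifts[, 1], dx = shifts[, 2]))
}

#' Rigid alignment between stimulus movies
#'
#' Aligns each movie's reference frame to the first movie's reference frame
#' with the same phase-correlation estimator and applies one constant shift
#' per movie, so that glomerulus maps derived from concatenated movies share
#' pixel coordinates.
#'
#' @param movies List of [dual_movie()] objects, already frame-registered.
#' @inheritParams register_movie
#' @return A list with `movies` (aligned) and `shifts` (tibble: movie index,
#'   `dy`, `dx`).
#' @export
align_movies <- function(movies, reference_frame = NULL, subpixel = FALSE) {
  stopifnot(length(movies) >= 1L, all(vapply(movies, inherits, TRUE, "dual_movie")))
  rf <- function(m) {
    i <- if (is.null(reference_frame)) max(0L, floor(m$odor_onset_frame / 2)) else reference_frame
    (m$f340[, , i + 1L] + m$f380[, , i + 1L]) / 2
  }
  ref <- rf(movies[[1]])
  shift_fun <- if (subpixel) shift_matrix_subpixel else shift_matrix
  shifts <- matrix(0, length(movies), 2)
  out <- movies
  for (j in seq_along(movies)[-1]) {
    s <- phase_shift(rf(movies[[j]]), ref, subpixel = subpixel)
    corr <- -s
    shifts[j, ] <- corr
    if (any(corr != 0)) {
      for (i in seq_len(dim(movies[[j]]$f340)[3])) {
        out[[j]]$f340[, , i] <- shift_fun(movies[[j]]$f340[, , i], corr[1], corr[2])
        out[[j]]$f380[, , i] <- shift_fun(movies[[j]]$f380[, , i], corr[1], corr[2])
      }
    }
  }
  list(movies = out,
       shifts = tibble(movie = seq_along(movies), dy = shifts[, 1], dx = shifts[, 2]))
}

#' Ratiometric signal with baseline subtraction
#'
#' Computes the FURA-2 ratio F340/F380 per pixel and frame and subtracts, per
#' pixel, the mean ratio over the first `n_baseline_frames` frames (the
#' pre-odor baseline), yielding the baseline-normalized response
#' \eqn{\Delta R}. The baseline must end at or before odor onset.
#'
#' @param movie A [dual_movie()]; F380 must be strictly positive.
#' @param n_baseline_frames Number of leading frames that define the baseline
#'   (default 40, i.e. 3.2 s at 80 ms frames).
#' @return A `ratio_movie` with array `delta_r` (`H x W x n_frames`); the mean
#'   of `delta_r` over the baseline frames is 0 for every pixel.
#' @export
compute_ratio <- function(movie, n_baseline_frames = 40) {
  stopifnot(inherits(movie, "dual_movie"))
  n_baseline_frames <- check_count(n_baseline_frames, "n_baseline_frames")
  if (n_baseline_frames > movie$odor_onset_frame) {
    stop_glomsep("baseline (%d frames) extends past odor onset (frame %d)",
                 n_baseline_frames, movie$odor_onset_frame)
  }
  bad <- which(movie$f380 <= 0)
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(movie$f380))
    stop_glomsep("F380 non-positive at %d pixel(s); first at (row %d, col %d, frame %d)",
                 length(bad), idx[1], idx[2], idx[3] - 1L)
  }
  ratio <- movie$f340 / movie$f380
  baseline <- apply(ratio[, , seq_len(n_baseline_frames), drop = FALSE], c(1, 2), mean)
  delta_r <- sweep(ratio, c(1, 2), baseline, "-")
  new_ratio_movie(delta_r, baseline_frames = seq_len(n_baseline_frames) - 1L,
                  frame_period = movie$frame_period,
                  odor_onset_frame = movie$odor_onset_frame,
                  odor_duration_frames = movie$odor_duration_frames,
                  stimulus = movie$stimulus)
}
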