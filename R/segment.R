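#' Glomerulus map
#'
#' A labeled ROI image: 0 = background, `k` = glomerulus `k`, labels
#' contiguous `1..n_glomeruli`. Build one with [detect_glomeruli()] or wrap a
#' user-supplied label image (e.g. manually traced ROIs) to bypass detection.
#'
#' @param labels Integer matrix of labels.
#' @param min_size Minimum ROI size in pixels; components smaller than this
#'   are removed (set `0` to keep everything).
#' @return An object of class `glom_map`.
#' @export
glom_map <- function(labels, min_size = 0L) {
  labels <- as.matrix(labels)
  if (any(labels < 0) || any(labels != round(labels))) {
    stop_glomsep("labels must be non-negative integers")
  }
  labels <- relabel_sequential(labels, min_size)
  structure(list(labels = labels, n_glomeruli = max(labels), min_size = min_size),
            class = "glom_map")
}

relabel_sequential <- function(labels, min_size) {
  tab <- table(labels[labels > 0])
  keep <- as.integer(names(tab)[tab >= min_size])
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (i in seq_along(keep)) out[labels == keep[i]] <- i
  out
}

#' @export
print.glom_map <- function(x, ...) {
  cat(sprintf("<glom_map> %d x %d px, %d glomeruli\n",
              nrow(x$labels), ncol(x$labels), x$n_glomeruli))
  invisible(x)
}

#' Detect glomerular ROIs by PCA and convex-cone factorization
#'
#' Implements the segmentation pipeline: (1) per-pixel Z-score of the time
#' series concatenated across all supplied stimulus movies; (2) spatial
#' Gaussian smoothing of every frame; (3) PCA of the pixels-by-time matrix,
#' retaining `k_components`; (4) convex-cone factorization in PCA space —
#' cone generators are selected greedily as the pixels with maximal residual
#' norm after projecting out previously selected generators; each pixel is
#' then assigned to the generator with the largest non-negative projection
#' coefficient of its (unsmoothed) Z-scored time series onto the generator's
#' reconstructed time course, provided that coefficient exceeds
#' `assign_threshold` times the generator's self-coefficient; (5) connected-
#' component cleanup discarding components below `min_size` pixels.
#'
#' Assignment uses the unsmoothed series so that sharp ROI boundaries are not
#' eroded by the blur (smoothing only stabilizes generator selection).
#'
#' @param movies A `ratio_movie` or list of co-registered `ratio_movie`s of
#'   identical spatial shape (one per stimulus).
#' @param k_components Number of principal components retained. The default
#'   `NULL` uses `min(30, numerical rank)`; an explicit value above the
#'   numerical rank is rejected.
#' @param sigma Gaussian smoothing bandwidth in pixels (default 2).
#' @param min_size Minimum ROI area in pixels (default 20).
#' @param assign_threshold Fraction of the generator self-coefficient a pixel
#'   must reach to be assigned (default 0.5).
#' @param min_corr Minimum Pearson correlation between a pixel's raw Z-scored
#'   series and the generator time course (default 0.5). Genuine ROI pixels
#'   correlate near 1 with their glomerulus' time course even at realistic
#'   noise; spurious generators arising from smoothing-correlated noise
#'   neighborhoods correlate only weakly (~ the central smoothing weight),
#'   so this criterion empties them before cleanup.
#' @param max_generators Upper bound on cone generators considered before
#'   cleanup (default 40).
#' @return A [glom_map()].
#' @export
detect_glomeruli <- function(movies, k_components = NULL, sigma = 2,
                             min_size = 20, assign_threshold = 0.5,
                             min_corr = 0.5, max_generators = 40) {
  if (inherits(movies, "ratio_movie")) movies <- list(movies)
  stopifnot(length(movies) >= 1L, all(vapply(movies, inherits, TRUE, "ratio_movie")))
  dims <- lapply(movies, function(m) dim(m$delta_r)[1:2])
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop_glomsep("all movies must share the same spatial shape")
  }
  auto_k <- is.null(k_components)
  if (!auto_k) k_components <- check_count(k_components, "k_components")
  min_size <- check_count(min_size, "min_size", min = 0L)
  H <- dims[[1]][1]; W <- dims[[1]][2]
  n_pix <- H * W

  # pixels x time, concatenated across stimuli
  x_raw <- do.call(cbind, lapply(movies, function(m) {
    matrix(m$delta_r, nrow = n_pix)
  }))
  n_t <- ncol(x_raw)

  # (1) per-pixel Z-score
  mu <- rowMeans(x_raw)
  s <- sqrt(pmax(rowMeans(x_raw^2) - mu^2, 0))
  s[s == 0] <- Inf
  x_z <- (x_raw - mu) / s

  # (2) spatial Gaussian smoothing per frame
  zs <- array(x_z, dim = c(H, W, n_t))
  zs <- EBImage::gblur(zs, sigma = sigma)
  x_s <- matrix(zs, nrow = n_pix)

  # (3) PCA (time-side eigendecomposition)
  if (!auto_k && k_components > min(n_pix, n_t)) {
    stop_glomsep("k_components (%d) exceeds the rank bound of the data (%d)",
                 k_components, min(n_pix, n_t))
  }
  cc <- crossprod(x_s)
  eg <- eigen(cc, symmetric = TRUE)
  num_rank <- sum(eg$values > max(eg$values[1], 0) * 1e-12)
  if (num_rank == 0L) {
    warn("data has no variance; returning empty map")
    return(glom_map(matrix(0L, H, W), min_size))
  }
  if (auto_k) {
    k_components <- min(30L, num_rank)
  } else if (k_components > num_rank) {
    stop_glomsep("k_components (%d) exceeds the numerical rank of the data (%d)",
                 k_components, num_rank)
  }
  v <- eg$vectors[, seq_len(k_components), drop = FALSE]
  scores <- x_s %*% v                      # pixels x k

  # (4) greedy cone-generator selection with Gram-Schmidt deflation
  res <- scores
  sel <- integer(0)
  init_norm <- NA_real_
  for (g in seq_len(max_generators)) {
    n2 <- rowSums(res^2)
    p <- which.max(n2)
    if (g == 1L) init_norm <- n2[p]
    if (n2[p] <= init_norm * 1e-10 || n2[p] == 0) break
    sel <- c(sel, p)
    u <- res[p, ] / sqrt(n2[p])
    res <- res - (res %*% u) %*% t(u)
  }
  if (!length(sel)) {
    warn("no cone generators found; returning empty map")
    return(glom_map(matrix(0L, H, W), min_size))
  }

  # generator time courses (reconstructed, denoised) and pixel coefficients
  # on the unsmoothed Z-scored data
  tg <- v %*% t(scores[sel, , drop = FALSE])           # time x G
  denom <- colSums(tg^2)
  coef <- (x_z %*% tg) / rep(denom, each = n_pix)
  self <- coef[cbind(sel, seq_along(sel))]
  ok <- self > 0
  if (!any(ok)) {
    warn("no valid generators after self-coefficient check; returning empty map")
    return(glom_map(matrix(0L, H, W), min_size))
  }
  coef <- coef[, ok, drop = FALSE]
  self <- self[ok]
  tg <- tg[, ok, drop = FALSE]
  rel <- sweep(coef, 2, self, "/")
  rel[coef <= 0] <- 0
  best <- max.col(rel, ties.method = "first")
  val <- rel[cbind(seq_len(n_pix), best)]
  # correlation gate: rows of x_z have mean 0 and population SD 1
  tgc <- sweep(tg, 2, colMeans(tg), "-")
  tg_norm <- sqrt(colSums(tgc^2))
  corr <- (x_z %*% tgc) / (sqrt(n_t) * rep(tg_norm, each = n_pix))
  corr[!is.finite(corr)] <- 0
  corr_best <- corr[cbind(seq_len(n_pix), best)]
  lab0 <- matrix(0L, H, W)
  assigned <- val >= assign_threshold & val > 0 & corr_best >= min_corr
  lab0[assigned] <- best[assigned]

  # (5) connected-component cleanup
  out <- matrix(0L, H, W)
  nxt <- 0L
  for (g in seq_len(ncol(rel))) {
    mask <- lab0 == g
    if (!any(mask)) next
    comp <- EBImage::bwlabel(mask)
    sizes <- table(comp[comp > 0])
    keep <- as.integer(names(sizes)[sizes >= min_size])
    keep <- keep[order(-sizes[as.character(keep)])]
    for (k in keep) {
      nxt <- nxt + 1L
      out[comp == k] <- nxt
    }
  }
  if (nxt == 0L) warn("no component survived the min_size threshold; map is empty")
  glom_map(out, min_size)
}

#' Extract per-glomerulus time courses
#'
#' The response of each glomerulus over time is the unweighted mean of
#' `delta_r` over all pixels carrying its label.
#'
#' @param map A [glom_map()].
#' @param movie A `ratio_movie` of the same spatial shape.
#' @return A [glom_traces()] (`n_glomeruli x n_frames`).
#' @export
extract_traces <- function(map, movie) {
  stopifnot(inherits(map, "glom_map"), inherits(movie, "ratio_movie"))
  d <- dim(movie$delta_r)
  if (!identical(dim(map$labels), d[1:2])) {
    stop_glomsep("map (%d x %d) and movie (%d x %d) shapes differ",
                 nrow(map$labels), ncol(map$labels), d[1], d[2])
  }
  if (map$n_glomeruli < 1L) stop_glomsep("map contains no glomeruli")
  x <- matrix(movie$delta_r, nrow = d[1] * d[2])
  lab <- as.vector(map$labels)
  vals <- matrix(0, map$n_glomeruli, d[3])
  for (k in seq_len(map$n_glomeruli)) {
    idx <- which(lab == k)
    if (!length(idx)) stop_glomsep("label %d has no pixels", k)
    vals[k, ] <- colMeans(x[idx, , drop = FALSE])
  }
  glom_traces(vals, stimulus = movie$stimulus, frame_period = movie$frame_period,
              odor_onset_frame = movie$odor_onset_frame,
              odor_duration_frames = movie$odor_duration_frames)
}

#' Overlap between a detected map and ground-truth labels
#'
#' Matches every ground-truth ROI to the detected label with the largest
#' Jaccard index (intersection over union). Used to score segmentation
#' recovery on synthetic movies.
#'
#' @param map A [glom_map()].
#' @param truth_labels Integer matrix of planted labels.
#' @return A tibble with `truth` (planted id), `detected` (best-matching
#'   label, 0 if none) and `jaccard`.
#' @export
map_overlap <- function(map, truth_labels) {
  stopifnot(inherits(map, "glom_map"))
  tl <- as.vector(truth_labels)
  dl <- as.vector(map$labels)
  ids <- sort(unique(tl[tl > 0]))
  rows <- lapply(ids, function(id) {
    mask <- tl == id
    cand <- unique(dl[mask & dl > 0])
    if (!length(cand)) return(tibble(truth = id, detected = 0L, jaccard = 0))
    j <- vapply(cand, function(k) {
      inter <- sum(mask & dl == k)
      uni <- sum(mask | dl == k)
      inter / uni
    }, numeric(1))
    b <- which.max(j)
    tibble(truth = id, detected = as.integer(cand[b]), jaccard = j[b])
  })
  dplyr::bind_rows(rows)
}
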