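#' Binary phase-plot image of a signal
#'
#' Embeds the signal as points \eqn{(s_i, s_{i+lag})} and marks every grid
#' cell the trajectory visits. The grid covers the square
#' \eqn{[-extent, extent]^2} with `n_grid` half-open bins per axis; since
#' segments are unit-variance, the default extent of 3 captures essentially
#' all samples, and outliers are clipped to the edge bins. Lag 1 and lag 5
#' are the two embeddings used for ventricular fibrillation detection (5
#' samples at 300 Hz unfolds the dynamics; 1 sample stays close to the
#' identity diagonal).
#'
#' The trajectory is rasterized the way a plotted phase portrait is: by
#' default consecutive embedded points are joined, so every grid cell a
#' connecting line segment passes through is marked, not only the cells the
#' samples themselves fall in (`connect = FALSE` gives the bare point
#' occupancy). Connected rasterization is what makes the diagonal-line
#' features meaningful: a smooth trajectory traced at finite sampling is
#' otherwise a chain of disconnected dots.
#'
#' @param x Numeric vector (typically one 2400-sample normalized segment).
#' @param lag Embedding delay in samples (>= 1, < `length(x)`).
#' @param n_grid Image resolution (pixels per side).
#' @param extent Half-width of the amplitude range binned.
#' @param connect Join consecutive trajectory points when rasterizing?
#' @return An `n_grid` x `n_grid` integer 0/1 matrix of class
#'   `phase_plot_image` with attributes `lag` and `extent`. Rows index the
#'   current value, columns the lagged value.
#' @examples
#' seg <- synth_ecg("vf", seed = 1)$record
#' img <- phase_plot(normalize_signal(seg$samples), lag = 5)
#' sum(img)  # occupied pixels
#' @export
phase_plot <- function(x, lag = 1L, n_grid = 100L, extent = 3,
                       connect = TRUE) {
  lag <- as.integer(lag)
  if (lag < 1L) ecg_abort("`lag` must be >= 1.", "config")
  n <- length(x)
  if (n <= lag) ecg_abort("`lag` must be smaller than the signal length.", "config")
  a <- x[seq_len(n - lag)]
  b <- x[seq_len(n - lag) + lag]
  to_bin <- function(v) {
    pmin(pmax(floor((v + extent) / (2 * extent) * n_grid) + 1L, 1L), n_grid)
  }
  r <- to_bin(a)
  cc <- to_bin(b)
  g <- matrix(0L, n_grid, n_grid)
  g[cbind(r, cc)] <- 1L
  if (connect && length(r) > 1L) {
    # join consecutive points: mark the cells an interpolating segment
    # crosses (one step per pixel along the longer axis)
    dr <- diff(r); dc <- diff(cc)
    steps <- pmax(abs(dr), abs(dc))
    for (i in which(steps > 1L)) {
      f <- seq(0, 1, length.out = steps[i] + 1L)
      g[cbind(as.integer(round(r[i] + f * dr[i])),
              as.integer(round(cc[i] + f * dc[i])))] <- 1L
    }
  }
  structure(g, class = c("phase_plot_image", "matrix", "array"),
            lag = lag, extent = extent)
}

#' @export
print.phase_plot_image <- function(x, ...) {
  cat(sprintf("<phase_plot_image> %dx%d, lag %d, %d occupied pixels (%.1f%%)\n",
              nrow(x), ncol(x), attr(x, "lag"), sum(x), 100 * mean(x)))
  invisible(x)
}

#' Self-similarity index of the two phase-plot images (feature F1)
#'
#' The difference `r2 - r1` between the occupied-pixel fractions of the
#' lag-5 and lag-1 images. Disorganized rhythms spread the lag-5 embedding
#' over many more cells than the lag-1 embedding, so the magnitude of the
#' difference grows with trajectory disorder.
#'
#' @param b1 Lag-1 [phase_plot()] image.
#' @param b2 Lag-5 [phase_plot()] image of the same segment and resolution.
#' @return Scalar in \[-1, 1\].
#' @export
self_similarity <- function(b1, b2) {
  check_same_resolution(b1, b2)
  lag1 <- attr(b1, "lag"); lag2 <- attr(b2, "lag")
  if (!is.null(lag1) && !is.null(lag2) && lag1 >= lag2) {
    ecg_abort("`b1` must be the shorter-lag image (lag 1) and `b2` the longer (lag 5).",
              "config")
  }
  mean(b2 == 1L) - mean(b1 == 1L)
}

#' Count 45-degree diagonal line structures (features F2 and F3)
#'
#' A line is a maximal run of foreground pixels along the main-diagonal
#' direction (row and column both increasing). Runs strictly longer than
#' `min_len` pixels are counted (F2) and their lengths summed (F3). Runs on
#' distinct diagonals are counted separately.
#'
#' @param mask Binary matrix (a [phase_plot()] image, typically the
#'   subtracted image).
#' @param min_len Minimum length threshold; runs must exceed it strictly.
#' @return A list with elements `count` (F2) and `pixels` (F3).
#' @export
diagonal_lines <- function(mask, min_len = 20L) {
  stopifnot(is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  count <- 0L; pixels <- 0L
  for (off in (-(h - 1L)):(w - 1L)) {
    r <- max(1L, 1L - off):min(h, w - off)
    v <- mask[cbind(r, r + off)]
    rl <- rle(v)
    lens <- rl$lengths[rl$values == 1L]
    keep <- lens > min_len
    count <- count + sum(keep)
    pixels <- pixels + sum(lens[keep])
  }
  list(count = as.integer(count), pixels = as.integer(pixels))
}

#' Subtract one binary image from another
#'
#' Pixel-wise `b1 AND NOT b2`; would-be negative pixels clamp to 0 so the
#' result stays binary.
#'
#' @param b1,b2 Binary matrices of the same resolution.
#' @return A binary matrix of class `phase_plot_image`.
#' @export
subtract_images <- function(b1, b2) {
  check_same_resolution(b1, b2)
  out <- matrix(as.integer(b1 == 1L & b2 != 1L), nrow(b1), ncol(b1))
  structure(out, class = c("phase_plot_image", "matrix", "array"),
            lag = NA_integer_, extent = attr(b1, "extent"))
}

check_same_resolution <- function(b1, b2) {
  if (!all(dim(b1) == dim(b2))) {
    ecg_abort("images have different resolutions.", "config")
  }
  invisible(TRUE)
}

#' Morphological hole filling of a binary image
#'
#' Background pixels not reachable from the image border through 4-connected
#' background paths are holes; they are switched to foreground. Implemented
#' as a breadth-first flood fill seeded on all border background pixels.
#'
#' @param mask Binary matrix.
#' @return Binary matrix with all enclosed holes set to 1.
#' @export
fill_holes <- function(mask) {
  stopifnot(is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  bg <- mask != 1L
  reach <- matrix(FALSE, h, w)
  border <- which((row(mask) == 1L | row(mask) == h |
                   col(mask) == 1L | col(mask) == w) & bg)
  reach[border] <- TRUE
  frontier <- border
  while (length(frontier)) {
    r <- (frontier - 1L) %% h + 1L
    cc <- (frontier - 1L) %/% h + 1L
    nb <- c(frontier[r > 1L] - 1L, frontier[r < h] + 1L,
            frontier[cc > 1L] - h, frontier[cc < w] + h)
    nb <- unique(nb[bg[nb] & !reach[nb]])
    reach[nb] <- TRUE
    frontier <- nb
  }
  out <- mask
  out[bg & !reach] <- 1L
  structure(out, class = class(mask), lag = attr(mask, "lag"),
            extent = attr(mask, "extent"))
}

#' Filled-pixel fraction after hole filling (feature F4)
#'
#' Applies [fill_holes()] and returns the foreground fraction of the result.
#' Reported as a fraction of the total pixel count so the feature is
#' comparable across image resolutions.
#'
#' @param mask Binary matrix (typically the subtracted phase-plot image).
#' @return Scalar in \[0, 1\].
#' @export
fill_fraction <- function(mask) {
  mean(fill_holes(mask) == 1L)
}

#' Image-based VF features of one segment (F1-F4)
#'
#' Builds the lag-1 and lag-5 phase-plot images, computes the
#' self-similarity index F1, and forms the difference image holding the
#' pixels unique to the lag-5 embedding (`subtract_images(B5, B1)`): the
#' 5-sample embedding is the one that unfolds disorganized dynamics, while
#' the near-diagonal lag-1 image acts as the organized-trajectory mask.
#' (The lag-5 image is always the larger set - the self-similarity index
#' `r5 - r1` is positive for every rhythm class - so the opposite clamped
#' difference would be nearly empty and carry no information.) The
#' diagonal-line features F2/F3 and the filled fraction F4 are computed on
#' that difference image.
#'
#' @param x Numeric vector: one normalized segment.
#' @param n_grid,extent Passed to [phase_plot()].
#' @param min_len Passed to [diagonal_lines()].
#' @return Named list with `f1`, `f2`, `f3`, `f4`.
#' @export
vf_image_features <- function(x, n_grid = 100L, extent = 3, min_len = 20L) {
  b1 <- phase_plot(x, lag = 1L, n_grid = n_grid, extent = extent)
  b5 <- phase_plot(x, lag = 5L, n_grid = n_grid, extent = extent)
  bdiff <- subtract_images(b5, b1)
  lines <- diagonal_lines(bdiff, min_len = min_len)
  list(f1 = self_similarity(b1, b5),
       f2 = lines$count,
       f3 = lines$pixels,
       f4 = fill_fraction(bdiff))
}

#' Stage-1 VF feature table for a set of segments
#'
#' Computes the six ventricular-fibrillation discrimination features per
#' segment: four image-based phase-plot features (F1 self-similarity, F2
#' diagonal-line count, F3 diagonal-line pixels, F4 filled fraction), the
#' spectral count F5 ([count_above_mean()] bins of the normalized amplitude
#' spectrum), and the amplitude Shannon entropy F6 ([shannon_entropy()]).
#'
#' @param segments Segment tibble from [segment_ecg()] (columns
#'   `segment_id`, `start_s`, `fs`, `samples`).
#' @param n_grid,extent,min_len Phase-plot image parameters.
#' @param n_bins Histogram bins for the entropy feature F6.
#' @return A tibble with columns `segment_id`, `start_s`, `f1` ... `f6`.
#' @examples
#' segs <- preprocess_ecg(synth_ecg("nsr", duration_s = 8, seed = 1)$record)
#' vf_features(segs)
#' @export
vf_features <- function(segments, n_grid = 100L, extent = 3, min_len = 20L,
                        n_bins = 16L) {
  check_segments(segments)
  feats <- map(segments$samples, function(x) {
    img <- vf_image_features(x, n_grid = n_grid, extent = extent,
                             min_len = min_len)
    spec <- amplitude_spectrum(x, fs = segments$fs[[1]])
    c(img, list(f5 = count_above_mean(spec$amp),
                f6 = shannon_entropy(x, n_bins = n_bins)))
  })
  tibble(
    segment_id = segments$segment_id,
    start_s = segments$start_s,
    f1 = map_dbl(feats, "f1"),
    f2 = map_int(feats, "f2"),
    f3 = map_int(feats, "f3"),
    f4 = map_dbl(feats, "f4"),
    f5 = map_int(feats, "f5"),
    f6 = map_dbl(feats, "f6")
  )
}

check_segments <- function(segments) {
  need <- c("segment_id", "start_s", "fs", "samples")
  if (!is.data.frame(segments) || !all(need %in% names(segments))) {
    ecg_abort("expected a segment tibble from segment_ecg().", "config")
  }
  invisible(TRUE)
}
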