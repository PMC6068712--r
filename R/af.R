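#' Exclude non-physiologic and ectopic RR intervals
#'
#' Two-step cleaning before the atrial-fibrillation features are computed:
#' intervals outside the physiologic range \[0.2, 3\] s are dropped, then
#' intervals deviating by more than 30% from the segment's median interval
#' are dropped. The second rule approximates premature-beat exclusion: a
#' premature beat produces one short and one long interval, both far from
#' the dominant interval, while genuine sinus variability stays within the
#' band. The reference is the global (whole-window) median rather than a
#' short running median: in bigeminy every other interval is ectopic, and a
#' running median locks onto the alternation itself, letting the classic
#' ectopic pattern through.
#'
#' @param rr Numeric vector of RR intervals in seconds (>= 3 values).
#' @return The retained intervals, in order.
#' @export
clean_rr <- function(rr) {
  if (length(rr) < 3L) ecg_abort("need at least 3 RR intervals.", "insufficient_beats")
  rr <- rr[rr >= 0.2 & rr <= 3]
  if (length(rr) >= 3L) {
    med <- median(rr)
    rr <- rr[abs(rr - med) <= 0.3 * med]
  }
  if (length(rr) < 3L) {
    ecg_abort("fewer than 3 RR intervals remain after cleaning.",
              "insufficient_beats")
  }
  rr
}

#' RMSSD of RR intervals, normalized by the mean interval
#'
#' Root mean square of successive RR differences divided by the mean RR, so
#' the irregularity measure transfers across heart rates.
#'
#' @param rr Numeric vector of RR intervals in seconds (>= 2 values).
#' @return Non-negative scalar.
#' @examples
#' rmssd_norm(c(0.8, 1.2))  # sqrt(0.16) / 1 = 0.4
#' @export
rmssd_norm <- function(rr) {
  if (length(rr) < 2L) ecg_abort("need at least 2 RR intervals.", "insufficient_beats")
  sqrt(mean(diff(rr)^2)) / mean(rr)
}

#' Turning point ratio of an RR series
#'
#' Fraction of interior points that are strict local maxima or minima.
#' Equal neighbours are treated as non-turning. For an independent random
#' sequence the expected ratio is 2/3; monotone sequences give 0 and
#' strictly alternating sequences give 1.
#'
#' @param rr Numeric vector (>= 3 values).
#' @return Scalar in \[0, 1\].
#' @export
turning_point_ratio <- function(rr) {
  n <- length(rr)
  if (n < 3L) ecg_abort("need at least 3 RR intervals.", "insufficient_beats")
  a <- rr[1:(n - 2)]; b <- rr[2:(n - 1)]; cc <- rr[3:n]
  turns <- (b > a & b > cc) | (b < a & b < cc)
  sum(turns) / (n - 2)
}

#' Normalized Shannon entropy of RR intervals
#'
#' Same histogram-entropy machinery as the segment-amplitude feature F6
#' ([shannon_entropy()]), applied to the RR series. Requires at least
#' `n_bins / 2` intervals; below that the histogram estimate is too
#' unstable to be meaningful.
#'
#' @param rr Numeric vector of RR intervals in seconds.
#' @param n_bins Number of histogram bins.
#' @return Scalar in \[0, 1\].
#' @export
rr_shannon_entropy <- function(rr, n_bins = 16L) {
  if (length(rr) < n_bins / 2) {
    ecg_abort(sprintf("need at least %d RR intervals for %d-bin entropy.",
                      ceiling(n_bins / 2), n_bins), "insufficient_beats")
  }
  shannon_entropy(rr, n_bins = n_bins)
}

#' Stage-2 AF feature table for a set of segments
#'
#' For each segment: detect R peaks, form RR intervals, exclude ectopic
#' intervals with [clean_rr()], then compute the three atrial-fibrillation
#' features - RR Shannon entropy (`se_rr`), turning point ratio (`tpr`) and
#' normalized RMSSD (`rmssd_n`). The entropy histogram uses 8 bins here
#' because an 8 s window holds only ~8-12 intervals. Segments with fewer
#' than `min_beats` detected peaks, or with fewer than `min_intervals`
#' cleaned RR intervals (variability statistics over a handful of
#' intervals are meaningless), are flagged `usable = FALSE` with `NA`
#' features rather than dropped.
#'
#' @param segments Segment tibble from [segment_ecg()].
#' @param min_beats Minimum number of detected R peaks.
#' @param min_intervals Minimum number of post-cleaning RR intervals.
#' @param n_bins Histogram bins for the RR entropy.
#' @return A tibble with columns `segment_id`, `start_s`, `se_rr`, `tpr`,
#'   `rmssd_n`, `n_beats`, `usable`.
#' @examples
#' segs <- preprocess_ecg(synth_ecg("af", duration_s = 8, seed = 2)$record)
#' af_features(segs)
#' @export
af_features <- function(segments, min_beats = 5L, min_intervals = 5L,
                        n_bins = 8L) {
  check_segments(segments)
  fs <- segments$fs[[1]]
  rows <- map(segments$samples, function(x) {
    peaks <- detect_r_peaks(x, fs = fs)
    out <- list(se_rr = NA_real_, tpr = NA_real_, rmssd_n = NA_real_,
                n_beats = length(peaks), usable = FALSE)
    if (length(peaks) < min_beats) return(out)
    res <- tryCatch({
      rr <- clean_rr(rr_intervals(peaks, fs = fs))
      if (length(rr) < min_intervals) {
        ecg_abort("too few cleaned RR intervals.", "insufficient_beats")
      }
      list(se_rr = rr_shannon_entropy(rr, n_bins = n_bins),
           tpr = turning_point_ratio(rr),
           rmssd_n = rmssd_norm(rr),
           n_beats = length(peaks), usable = TRUE)
    }, ecgkit_insufficient_beats = function(e) NULL)
    res %||% out
  })
  tibble(
    segment_id = segments$segment_id,
    start_s = segments$start_s,
    se_rr = map_dbl(rows, "se_rr"),
    tpr = map_dbl(rows, "tpr"),
    rmssd_n = map_dbl(rows, "rmssd_n"),
    n_beats = map_int(rows, "n_beats"),
    usable = purrr::map_lgl(rows, "usable")
  )
}
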