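#' Detect R peaks in an ECG segment
#'
#' Pan-Tompkins-style pipeline: first difference, squaring, 150 ms
#' moving-window integration, then peak picking on the integrated signal
#' with an adaptive threshold (initialized from the first two seconds and
#' updated as `0.125 * peak + 0.875 * threshold`) and a 200 ms refractory
#' period. Each integrated-signal peak is refined to the local maximum of
#' the raw signal in a 150 ms look-back window, where the R wave sits.
#'
#' @param x Numeric vector: one (band-passed, normalized) segment.
#' @param fs Sampling rate in Hz.
#' @param refractory_s Minimum distance between successive peaks, seconds.
#' @return Strictly increasing integer vector of R sample indices; empty
#'   when no peak clears the threshold (e.g. a flat segment).
#' @examples
#' seg <- preprocess_ecg(synth_ecg("nsr", hr_bpm = 60, seed = 1)$record)
#' detect_r_peaks(seg$samples[[1]], fs = 300)
#' @export
detect_r_peaks <- function(x, fs = 300, refractory_s = 0.2) {
  n <- length(x)
  if (n < fs) return(integer(0))
  if (max(x) - min(x) < 1e-12) return(integer(0))
  d <- c(0, diff(x))
  sq <- d^2
  w <- max(1L, as.integer(round(0.15 * fs)))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0
  init <- mwi[seq_len(min(n, as.integer(2 * fs)))]
  spk <- max(init)                 # running signal-peak estimate
  npk <- mean(init)                # running noise-peak estimate
  if (spk <= 0) spk <- max(mwi)
  if (spk <= 0) return(integer(0))
  thr <- function() npk + 0.25 * (spk - npk)
  floor_thr <- 0.05 * max(mwi)
  refr <- as.integer(round(refractory_s * fs))
  # local maxima of the integrated signal
  is_peak <- c(FALSE, mwi[2:(n - 1)] >= mwi[1:(n - 2)] &
                      mwi[2:(n - 1)] > mwi[3:n], FALSE)
  cand <- which(is_peak)
  peaks <- integer(0)
  for (i in cand) {
    if (mwi[i] < max(thr(), floor_thr)) {
      npk <- 0.125 * mwi[i] + 0.875 * npk
      next
    }
    # refine: R peak is the raw-signal maximum just before/at the MWI crest
    lo <- max(1L, i - as.integer(round(0.15 * fs)))
    hi <- min(n, i + as.integer(round(0.05 * fs)))
    r <- lo + which.max(x[lo:hi]) - 1L
    if (length(peaks) && r - peaks[length(peaks)] < refr) {
      # two triggers inside the refractory (e.g. a tall P or T wave next to
      # the R): keep the larger raw-amplitude one
      if (x[r] > x[peaks[length(peaks)]]) peaks[length(peaks)] <- r else next
    } else {
      peaks <- c(peaks, r)
    }
    spk <- 0.125 * mwi[i] + 0.875 * spk
  }
  peaks <- unique(peaks)
  # amplitude plausibility: a genuine R wave is not a small fraction of its
  # neighbours (guards against window-edge and T-wave triggers)
  if (length(peaks) >= 3L) {
    peaks <- peaks[x[peaks] >= 0.3 * median(x[peaks])]
  }
  peaks
}

#' RR intervals from R-peak indices
#'
#' @param r_indices Strictly increasing R-peak sample indices.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of successive R-to-R intervals in seconds.
#' @export
rr_intervals <- function(r_indices, fs = 300) {
  if (length(r_indices) < 2L) return(numeric(0))
  diff(r_indices) / fs
}
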