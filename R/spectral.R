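#' Single-sided amplitude spectrum
#'
#' FFT of the full window (no zero padding, rectangular window), folded to a
#' single-sided amplitude spectrum. For a 2400-sample segment at 300 Hz the
#' resolution is 0.125 Hz with 1201 bins spanning 0-150 Hz. By default the
#' amplitudes are normalized to a unit maximum, which makes the derived
#' count feature F5 scale-invariant; beat-level analysis uses the raw
#' amplitudes instead (see [beat_msa()]).
#'
#' @param x Numeric vector (not all zero).
#' @param fs Sampling rate in Hz.
#' @param normalize Divide amplitudes by their maximum?
#' @return A tibble with columns `freq` (Hz) and `amp`, and attribute `df`
#'   (bin width in Hz).
#' @examples
#' spec <- amplitude_spectrum(sin(2 * pi * 5 * (0:2399) / 300), fs = 300)
#' attr(spec, "df")
#' spec$freq[which.max(spec$amp)]
#' @export
amplitude_spectrum <- function(x, fs, normalize = TRUE) {
  n <- length(x)
  if (n < 2L) ecg_abort("need at least 2 samples.", "config")
  if (all(x == 0)) ecg_abort("all-zero signal has no spectrum.", "degenerate")
  A <- Mod(fft(x)) / n
  half <- n %/% 2L + 1L
  amp <- A[seq_len(half)]
  # double everything except DC (and Nyquist for even n): single-sided fold
  top <- if (n %% 2L == 0L) half - 1L else half
  if (top >= 2L) amp[2:top] <- 2 * amp[2:top]
  if (normalize) amp <- amp / max(amp)
  structure(tibble(freq = (seq_len(half) - 1L) * fs / n, amp = amp),
            df = fs / n)
}

#' Count spectral bins above the mean amplitude (feature F5)
#'
#' The number of frequency bins whose amplitude strictly exceeds the mean
#' amplitude over the whole single-sided spectrum. Spiky broadband rhythms
#' (discrete QRS complexes) put many harmonics above the mean; narrowband
#' disorganized rhythms concentrate power in few bins.
#'
#' @param amp Amplitude vector (or a spectrum tibble's `amp` column).
#' @param fmax Optional upper frequency cut; requires `freq` alongside, so
#'   pass the spectrum tibble itself when using it.
#' @return Integer count.
#' @export
count_above_mean <- function(amp, fmax = NULL) {
  if (is.data.frame(amp)) {
    spec <- amp
    if (!is.null(fmax)) spec <- spec[spec$freq <= fmax, ]
    amp <- spec$amp
  } else if (!is.null(fmax)) {
    ecg_abort("`fmax` needs a spectrum tibble with a `freq` column.", "config")
  }
  sum(amp > mean(amp))
}

#' Normalized Shannon entropy of an amplitude histogram (feature F6)
#'
#' Histogram of the sample amplitudes over their own range in `n_bins`
#' equal-width bins; entropy \eqn{-\sum p_i \log_2 p_i} with empty bins
#' contributing zero, divided by \eqn{\log_2 n_{bins}} so the result lies in
#' \[0, 1\] (1 = uniform occupancy, 0 = a single occupied bin). Because the
#' histogram spans the data range, the value is invariant to affine
#' amplitude rescaling. Constant input returns 0.
#'
#' @param x Numeric vector.
#' @param n_bins Number of histogram bins (>= 2).
#' @param normalize Divide by `log2(n_bins)`?
#' @return Scalar entropy (bits if `normalize = FALSE`).
#' @examples
#' shannon_entropy(rep(1:16, each = 10))  # uniform occupancy -> 1
#' shannon_entropy(rep(2, 50))            # constant -> 0
#' @export
shannon_entropy <- function(x, n_bins = 16L, normalize = TRUE) {
  if (n_bins < 2L) ecg_abort("`n_bins` must be >= 2.", "config")
  if (length(x) < n_bins && length(x) < 2L) {
    ecg_abort("too few samples for an entropy estimate.", "config")
  }
  rng <- range(x)
  if (diff(rng) == 0) return(0)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), n_bins)
  p <- tabulate(idx, n_bins) / length(x)
  p <- p[p > 0]
  h <- -sum(p * log2(p))
  if (normalize) h / log2(n_bins) else h
}
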