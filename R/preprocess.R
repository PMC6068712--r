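#' Resample an ECG record to a target rate
#'
#' Fourier-domain resampling: the spectrum is truncated or zero-padded to the
#' new length, which is exact for band-limited content and introduces only
#' edge ringing on non-periodic records (negligible after band-pass
#' filtering). Output length is `round(n * fs_target / fs)`. A no-op when the
#' record is already at the target rate.
#'
#' @param record An [ecg_record()].
#' @param fs_target Target sampling rate in Hz; the pipeline standard is 300.
#' @return An [ecg_record()] at `fs_target`.
#' @export
resample_ecg <- function(record, fs_target = 300) {
  stopifnot(inherits(record, "ecg_record"))
  if (record$fs == fs_target) return(record)
  x <- record$samples
  n <- length(x)
  m <- round(n * fs_target / record$fs)
  X <- fft(x)
  Y <- complex(m)
  n2 <- min(n, m)
  half <- n2 %/% 2L
  nneg <- if (n2 %% 2L == 0L) half - 1L else half  # negative-frequency bins kept
  Y[seq_len(half + 1L)] <- X[seq_len(half + 1L)]
  if (nneg > 0L) Y[m - seq_len(nneg) + 1L] <- X[n - seq_len(nneg) + 1L]
  if (n2 %% 2L == 0L) {
    # shared Nyquist bin: fold when decimating, split when interpolating,
    # keeping conjugate symmetry so the result is real
    if (m < n) {
      Y[half + 1L] <- X[half + 1L] + X[n - half + 1L]
    } else if (m > n) {
      Y[half + 1L] <- X[half + 1L] / 2
      Y[m - half + 1L] <- Conj(X[half + 1L] / 2)
    }
  }
  y <- Re(fft(Y, inverse = TRUE)) * (m / n) / m
  ecg_record(y, fs = fs_target, record_id = record$record_id)
}

#' Band-pass filter an ECG record
#'
#' Third-order Butterworth band-pass (defaults 0.4-30 Hz) applied
#' forward-backward ([signal::filtfilt()]) so the QRS morphology is not
#' phase-distorted.
#'
#' @param record An [ecg_record()].
#' @param low,high Cut-off frequencies in Hz.
#' @param order Filter order.
#' @return A filtered [ecg_record()] at the same rate.
#' @export
bandpass_ecg <- function(record, low = 0.4, high = 30, order = 3) {
  stopifnot(inherits(record, "ecg_record"))
  if (record$fs <= 2 * high) {
    ecg_abort("sampling rate must exceed twice the high cut-off.", "config")
  }
  bf <- signal::butter(order, c(low, high) / (record$fs / 2), type = "pass")
  y <- zero_phase_filter(bf$b, bf$a, record$samples)
  ecg_record(y, fs = record$fs, record_id = record$record_id,
             annotations = record$annotations)
}

# steady-state initial filter state for a step of unit amplitude, so the
# filter starts transient-free (the classic Matlab/scipy filtfilt trick)
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n))[1:n]
  a <- c(a, rep(0, n))[1:n]
  b <- b / a[1]; a <- a / a[1]
  A <- matrix(0, n - 1, n - 1)
  A[1, ] <- -a[2:n]
  if (n > 2) A[cbind(2:(n - 1), 1:(n - 2))] <- 1
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - t(A), B)
}

# IIR filtering in direct form II transposed with explicit initial state
# (Matlab/scipy zi convention)
lfilter_state <- function(b, a, x, zi) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf))[1:nf]
  a <- c(a, rep(0, nf))[1:nf]
  b <- b / a[1]; a <- a / a[1]
  y <- numeric(length(x))
  z <- c(zi, 0)
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    for (j in seq_len(nf - 1)) {
      z[j] <- b[j + 1] * x[i] + z[j + 1] - a[j + 1] * y[i]
    }
  }
  y
}

# forward-backward filtering with odd-reflection padding and steady-state
# initialization at both ends; mirrors the behaviour of scipy's filtfilt
zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  p <- min(n - 1L, 3L * max(length(a), length(b)))
  ext <- c(2 * x[1] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  zi <- lfilter_zi(b, a)
  y <- lfilter_state(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- rev(lfilter_state(b, a, y, zi * y[1]))
  y[(p + 1L):(p + n)]
}

#' Normalize a signal to zero mean and unit variance
#'
#' Population (1/N) variance is used so the scaling is a fixed function of
#' the window, independent of sample-variance conventions.
#'
#' @param x Numeric vector with positive variance.
#' @return Numeric vector with mean 0 and population variance 1.
#' @examples
#' normalize_signal(c(1, 3))
#' @export
normalize_signal <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v <= 0 || !is.finite(v)) {
    ecg_abort("cannot normalize a constant (zero-variance) signal.", "degenerate")
  }
  (x - m) / sqrt(v)
}

#' Cut a 300 Hz record into overlapping, normalized 8 s segments
#'
#' Windows of `seg_len_s` seconds are taken every `seg_len_s - overlap_s`
#' seconds (defaults: 8 s windows every 5 s). Each window is normalized to
#' zero mean and unit variance *after* cutting, which is what the phase-plot
#' binning assumes. Constant windows are rejected.
#'
#' @param record An [ecg_record()] at 300 Hz (run [resample_ecg()] first).
#' @param seg_len_s Window length in seconds.
#' @param overlap_s Overlap between consecutive windows in seconds
#'   (must be < `seg_len_s`).
#' @return A tibble with one row per segment: `segment_id`, `start_s`, `fs`,
#'   and `samples` (list-column of length-2400 numeric vectors).
#' @examples
#' rec <- synth_ecg("nsr", duration_s = 24, seed = 1)$record
#' segs <- segment_ecg(bandpass_ecg(resample_ecg(rec)))
#' segs
#' @export
segment_ecg <- function(record, seg_len_s = 8, overlap_s = 3) {
  stopifnot(inherits(record, "ecg_record"))
  if (record$fs != 300) {
    ecg_abort("segment_ecg() expects a 300 Hz record; run resample_ecg() first.",
              "config")
  }
  if (overlap_s >= seg_len_s) ecg_abort("`overlap_s` must be < `seg_len_s`.", "config")
  fs <- record$fs
  win <- as.integer(round(seg_len_s * fs))
  step <- as.integer(round((seg_len_s - overlap_s) * fs))
  n <- length(record$samples)
  if (n < win) {
    ecg_abort(sprintf("record (%.2f s) is shorter than one %g s segment.",
                      n / fs, seg_len_s), "too_short")
  }
  starts <- seq.int(0L, n - win, by = step)
  tibble(
    segment_id = seq_along(starts),
    start_s = starts / fs,
    fs = fs,
    samples = lapply(starts, function(s0) {
      normalize_signal(record$samples[(s0 + 1L):(s0 + win)])
    })
  )
}

#' Run the full preprocessing chain on a raw record
#'
#' Convenience wrapper: resample to 300 Hz, 0.4-30 Hz Butterworth band-pass,
#' then overlapping normalized segmentation.
#'
#' @inheritParams segment_ecg
#' @param record An [ecg_record()] at any sampling rate.
#' @return The segment tibble of [segment_ecg()].
#' @export
preprocess_ecg <- function(record, seg_len_s = 8, overlap_s = 3) {
  record |>
    resample_ecg(300) |>
    bandpass_ecg() |>
    segment_ecg(seg_len_s = seg_len_s, overlap_s = overlap_s)
}
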