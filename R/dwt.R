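# Daubechies-4 (8-tap) orthonormal scaling filter; the wavelet filter is its
# quadrature mirror. Coefficients sum to sqrt(2).
DB4_H <- c(0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
           -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
           0.03288301166698295, -0.01059740178499728)
DB4_G <- rev(DB4_H) * c(1, -1)

# one analysis step: symmetric (half-point) extension, filter, dyadic
# downsample; output length floor((n + filter_len - 1) / 2)
dwt_step <- function(x, h) {
  L <- length(h)
  n <- length(x)
  ext <- c(rev(x[seq_len(L - 1L)]), x, rev(x[n - seq_len(L - 1L) + 1L]))
  full <- stats::convolve(ext, rev(h), type = "filter")  # length n + L - 1
  full[seq.int(2L, length(full), by = 2L)]
}

#' Discrete wavelet decomposition (Daubechies-4)
#'
#' Pyramid analysis with the 8-tap Daubechies-4 filter pair and symmetric
#' boundary extension. Returns the approximation at the deepest level plus
#' the detail coefficients of every level.
#'
#' @param x Numeric vector (length must stay >= the filter length at every
#'   level; 4 levels need at least ~64 samples).
#' @param levels Number of decomposition levels.
#' @return A list with elements `approx` (numeric vector) and `details`
#'   (list of numeric vectors, level 1 = finest first).
#' @export
dwt_db4 <- function(x, levels = 4L) {
  a <- x
  details <- vector("list", levels)
  for (lev in seq_len(levels)) {
    if (length(a) < length(DB4_H)) {
      ecg_abort("signal too short for the requested decomposition depth.",
                "config")
    }
    details[[lev]] <- dwt_step(a, DB4_G)
    a <- dwt_step(a, DB4_H)
  }
  list(approx = a, details = details)
}

#' Wavelet Shannon entropy of a beat
#'
#' Energy distribution entropy of the Daubechies-4 wavelet coefficients:
#' after a `levels`-deep decomposition, each coefficient contributes
#' \eqn{p_i = c_i^2 / \sum_j c_j^2}, and the Shannon entropy of the
#' \eqn{p_i} is normalized by \eqn{\log_2} of the coefficient count, giving
#' a value in \[0, 1\]. Narrow transient beats concentrate energy in few
#' coefficients (low entropy); noise-like beats spread it (high entropy).
#' Invariant to amplitude scaling.
#'
#' @param x Numeric vector (one 200-sample beat window).
#' @param levels Decomposition depth.
#' @return Scalar in \[0, 1\].
#' @export
wavelet_entropy <- function(x, levels = 4L) {
  dec <- dwt_db4(x, levels = levels)
  co <- c(dec$approx, unlist(dec$details))
  e <- co^2
  tot <- sum(e)
  if (tot <= 0) ecg_abort("degenerate (all-zero) beat.", "degenerate")
  p <- e / tot
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(length(co))
}
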