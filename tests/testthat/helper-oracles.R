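# Independent brute-force oracles used to validate the fast implementations.
# Each is written as a plain scan/loop, deliberately sharing no code with the
# package internals.

oracle_diagonal_lines <- function(mask, min_len) {
  h <- nrow(mask); w <- ncol(mask)
  count <- 0L; pixels <- 0L
  for (off in (-(h - 1)):(w - 1)) {
    run <- 0L
    rs <- max(1, 1 - off):min(h, w - off)
    for (r in rs) {
      if (mask[r, r + off] == 1) {
        run <- run + 1L
      } else {
        if (run > min_len) { count <- count + 1L; pixels <- pixels + run }
        run <- 0L
      }
    }
    if (run > min_len) { count <- count + 1L; pixels <- pixels + run }
  }
  list(count = count, pixels = pixels)
}

oracle_subtract <- function(b1, b2) {
  out <- matrix(0L, nrow(b1), ncol(b1))
  for (i in seq_len(nrow(b1))) {
    for (j in seq_len(ncol(b1))) {
      out[i, j] <- max(b1[i, j] - b2[i, j], 0L)
    }
  }
  out
}

# scalar queue-based flood fill from the border (contrast with the package's
# vectorized frontier propagation)
oracle_fill <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  reach <- matrix(FALSE, h, w)
  queue <- integer(0)
  for (r in 1:h) for (cc in 1:w) {
    if ((r == 1 || r == h || cc == 1 || cc == w) && mask[r, cc] == 0) {
      queue <- c(queue, (cc - 1L) * h + r)
      reach[r, cc] <- TRUE
    }
  }
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    r <- (id - 1L) %% h + 1L; cc <- (id - 1L) %/% h + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      nr <- r + d[1]; nc <- cc + d[2]
      if (nr >= 1 && nr <= h && nc >= 1 && nc <= w &&
          mask[nr, nc] == 0 && !reach[nr, nc]) {
        reach[nr, nc] <- TRUE
        queue <- c(queue, (nc - 1L) * h + nr)
      }
    }
  }
  out <- mask
  out[mask == 0 & !reach] <- 1L
  out
}

oracle_count_above_mean <- function(amp) {
  m <- sum(amp) / length(amp)
  n <- 0L
  for (a in amp) if (a > m) n <- n + 1L
  n
}

oracle_entropy <- function(x, n_bins, normalize = TRUE) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(0)
  counts <- rep(0L, n_bins)
  for (v in x) {
    b <- floor((v - lo) / (hi - lo) * n_bins) + 1
    if (b > n_bins) b <- n_bins
    counts[b] <- counts[b] + 1L
  }
  h <- 0
  for (cnt in counts) {
    if (cnt > 0) {
      p <- cnt / length(x)
      h <- h - p * log2(p)
    }
  }
  if (normalize) h / log2(n_bins) else h
}

oracle_tpr <- function(rr) {
  t <- 0L
  for (i in 2:(length(rr) - 1)) {
    if ((rr[i] > rr[i - 1] && rr[i] > rr[i + 1]) ||
        (rr[i] < rr[i - 1] && rr[i] < rr[i + 1])) t <- t + 1L
  }
  t / (length(rr) - 2)
}

oracle_rmssd_norm <- function(rr) {
  s <- 0
  for (i in 2:length(rr)) s <- s + (rr[i] - rr[i - 1])^2
  sqrt(s / (length(rr) - 1)) / (sum(rr) / length(rr))
}

oracle_kurtosis <- function(x) {
  mu <- sum(x) / length(x)
  m2 <- sum((x - mu)^2) / length(x)
  m4 <- sum((x - mu)^4) / length(x)
  m4 / m2^2
}

# single-segment convenience: preprocess a fresh synthetic record and keep
# the first window
synth_segment <- function(rhythm, seed, hr_bpm = 70, noise_sd = 0.02) {
  rec <- synth_ecg(rhythm, duration_s = 8, hr_bpm = hr_bpm,
                   noise_sd = noise_sd, seed = seed)$record
  preprocess_ecg(rec)[1, ]
}

random_mask <- function(n = 100, p = 0.2) {
  matrix(rbinom(n * n, 1L, p), n, n)
}
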