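test_that("beat windows span [r-70, r+129] and boundary beats are skipped", {
  x <- rnorm(2400)
  b <- cut_beats(x, c(50L, 71L, 1000L, 2271L, 2272L))
  # r = 50 reaches 20 samples left of the segment; r = 2272 one past the end
  expect_length(b, 3)
  expect_equal(attr(b, "skipped"), 2)
  expect_equal(attr(b, "r_indices"), c(71L, 1000L, 2271L))
  expect_equal(b[[1]], x[1:200])
  expect_equal(b[[2]], x[930:1129])
  expect_true(all(lengths(b) == 200))
})

test_that("LMMD is the window peak-to-valley excursion", {
  beat <- c(rep(0, 50), 1.2, rep(0, 100), -0.4, rep(0, 48))
  expect_equal(lmmd(beat), 1.6)
  expect_equal(lmmd(rep(0.7, 200)), 0)
})

test_that("MSA equals the closed-form tone amplitude and scales linearly", {
  t <- (0:199) / 300
  beat <- sin(2 * pi * 6 * t)  # 6 Hz = bin 4 of a 200-point, 1.5 Hz grid
  m <- beat_msa(beat, fs = 300)
  # closed-form DFT magnitude of an on-bin unit tone, single-sided
  k <- 6 / (300 / 200)
  oracle <- 2 * Mod(sum(beat * exp(-2i * pi * k * (0:199) / 200))) / 200
  expect_equal(m, oracle, tolerance = 1e-9)
  expect_equal(beat_msa(2 * beat, fs = 300), 2 * m, tolerance = 1e-9)
})

test_that("wavelet entropy: impulse is concentrated, noise is spread", {
  imp <- numeric(200); imp[71] <- 1
  wi <- wavelet_entropy(imp)
  expect_lt(wi, 0.4)
  for (seed in 1:10) {
    set.seed(seed)
    expect_gt(wavelet_entropy(rnorm(200)), wi)
  }
  expect_error(wavelet_entropy(numeric(200)), class = "ecgkit_degenerate")
})

test_that("wavelet entropy equals the brute-force coefficient entropy", {
  set.seed(47)
  for (i in 1:20) {
    x <- rnorm(200) * runif(1, 0.1, 10)
    dec <- dwt_db4(x, 4)
    co <- c(dec$approx, unlist(dec$details))
    p <- co^2 / sum(co^2)
    manual <- 0
    for (pp in p) if (pp > 0) manual <- manual - pp * log2(pp)
    expect_equal(wavelet_entropy(x), manual / log2(length(co)),
                 tolerance = 1e-9)
  }
})

test_that("kurtosis calibrates on the normal distribution and matches oracles", {
  set.seed(53)
  expect_equal(beat_kurtosis(rnorm(1e5)), 3, tolerance = 0.1)
  expect_equal(beat_kurtosis(rep(c(-1, 1), 100)), 1)
  for (i in 1:50) {
    x <- rnorm(sample(50:400, 1)) * runif(1, 0.2, 5)
    expect_equal(beat_kurtosis(x), oracle_kurtosis(x), tolerance = 1e-9)
    expect_equal(beat_kurtosis(x), e1071::kurtosis(x, type = 1) + 3,
                 tolerance = 1e-9)
  }
  expect_error(beat_kurtosis(rep(1, 200)), class = "ecgkit_degenerate")
})

test_that("kurt and wse are scale-invariant; lmmd and msa scale linearly", {
  set.seed(59)
  x <- rnorm(200)
  expect_equal(beat_kurtosis(3 * x), beat_kurtosis(x), tolerance = 1e-9)
  expect_equal(wavelet_entropy(3 * x), wavelet_entropy(x), tolerance = 1e-9)
  expect_equal(lmmd(3 * x), 3 * lmmd(x), tolerance = 1e-12)
  expect_equal(beat_msa(3 * x), 3 * beat_msa(x), tolerance = 1e-9)
})

test_that("PVC beats have larger LMMD and MSA than normal beats", {
  wins_lmmd <- 0L; wins_msa <- 0L; pairs <- 0L
  seed <- 60L
  while (pairs < 20L) {
    seed <- seed + 1L
    s <- synth_ecg("bg", duration_s = 16, hr_bpm = 70, seed = seed)
    segs <- preprocess_ecg(s$record)
    beats <- extract_beats(segs[1, ])
    truth <- ecgkit:::match_beat_truth(beats, segs, s$beats)
    f <- pvc_features(beats)
    pv <- which(truth == 1L); nn <- which(truth == 0L)
    take <- min(length(pv), length(nn), 20L - pairs)
    if (take == 0L) next
    for (j in seq_len(take)) {
      pairs <- pairs + 1L
      wins_lmmd <- wins_lmmd + (f$lmmd[pv[j]] > f$lmmd[nn[j]])
      wins_msa <- wins_msa + (f$msa[pv[j]] > f$msa[nn[j]])
    }
  }
  expect_gte(wins_lmmd, 18L)
  expect_gte(wins_msa, 18L)
})
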