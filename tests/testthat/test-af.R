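test_that("R-peak detection counts beats correctly at 60 and 100 bpm", {
  for (seed in 1:5) {
    s60 <- synth_ecg("nsr", hr_bpm = 60, seed = seed)
    seg <- preprocess_ecg(s60$record)
    pk <- detect_r_peaks(seg$samples[[1]], fs = 300)
    expect_gte(length(pk), 7); expect_lte(length(pk), 9)
    # every scheduled beat clear of the edges is found within 25 ms
    truth <- s60$beats$time_s[s60$beats$time_s > 0.3 & s60$beats$time_s < 7.8]
    for (tt in truth) expect_lt(min(abs(pk / 300 - tt)), 0.025)

    s100 <- synth_ecg("nsr", hr_bpm = 100, seed = seed + 50)
    pk100 <- detect_r_peaks(preprocess_ecg(s100$record)$samples[[1]], fs = 300)
    expect_gte(length(pk100), 12); expect_lte(length(pk100), 14)
  }
  expect_identical(detect_r_peaks(rep(0, 2400), fs = 300), integer(0))
})

test_that("RR cleaning removes sub-physiologic and ectopic intervals", {
  expect_equal(clean_rr(c(0.8, 0.8, 0.05, 0.8, 0.8)), rep(0.8, 4))
  expect_equal(clean_rr(rep(0.9, 6)), rep(0.9, 6))
  # one 50% outlier against a steady 0.8 baseline
  rr <- c(0.8, 0.8, 0.8, 1.2, 0.8, 0.8, 0.8)
  expect_equal(clean_rr(rr), rep(0.8, 6))
  expect_error(clean_rr(c(0.8, 0.9)), class = "ecgkit_insufficient_beats")
  expect_error(clean_rr(c(0.05, 0.06, 0.07)), class = "ecgkit_insufficient_beats")
})

test_that("normalized RMSSD matches closed forms and the loop oracle", {
  expect_equal(rmssd_norm(c(1, 1, 1, 1)), 0)
  expect_equal(rmssd_norm(c(0.8, 1.2)), 0.4)
  set.seed(31)
  for (i in 1:100) {
    rr <- runif(sample(5:50, 1), 0.4, 1.2)
    expect_equal(rmssd_norm(rr), oracle_rmssd_norm(rr), tolerance = 1e-9)
  }
  expect_error(rmssd_norm(0.8), class = "ecgkit_insufficient_beats")
})

test_that("turning point ratio: monotone 0, alternating 1, iid mean 2/3", {
  expect_equal(turning_point_ratio(seq(0.5, 1.5, by = 0.1)), 0)
  expect_equal(turning_point_ratio(rep(c(0.8, 1.2), 10)), 1)
  set.seed(37)
  for (i in 1:100) {
    rr <- runif(sample(5:50, 1))
    expect_equal(turning_point_ratio(rr), oracle_tpr(rr), tolerance = 1e-9)
  }
  # combinatorial expectation: interior points of an iid sequence turn w.p. 2/3
  set.seed(41)
  tprs <- replicate(1000, turning_point_ratio(runif(200)))
  expect_equal(mean(tprs), 2 / 3, tolerance = 0.02)
  expect_error(turning_point_ratio(c(1, 2)), class = "ecgkit_insufficient_beats")
})

test_that("RR entropy guards its sample size and hits the extremes", {
  expect_equal(rr_shannon_entropy(rep(0.8, 20)), 0)
  expect_equal(rr_shannon_entropy(rep(seq(0.4, 1.2, length.out = 16), 3)), 1)
  expect_error(rr_shannon_entropy(runif(5), n_bins = 16),
               class = "ecgkit_insufficient_beats")
  set.seed(43)
  for (i in 1:50) {
    rr <- runif(20, 0.4, 1.2)
    expect_equal(rr_shannon_entropy(rr), oracle_entropy(rr, 16),
                 tolerance = 1e-9)
  }
})

test_that("AF features separate synthetic AF from NSR and see only RR", {
  tprs <- c()
  usable_af <- 0L
  for (seed in 1:10) {
    fn <- af_features(synth_segment("nsr", seed = seed))
    fa <- af_features(synth_segment("af", seed = seed + 300))
    expect_true(fn$usable)
    expect_lt(fn$rmssd_n, 0.1)
    if (!fa$usable) next  # irregularity can leave too few cleaned intervals
    usable_af <- usable_af + 1L
    expect_gt(fa$rmssd_n, 0.05)
    expect_gt(fa$rmssd_n, 3 * fn$rmssd_n)
    tprs <- c(tprs, fa$tpr)
  }
  expect_gte(usable_af, 8L)
  # with only ~6-10 cleaned intervals per window the per-segment TPR is
  # coarse; its average should sit near the 2/3 iid expectation
  expect_gt(mean(tprs), 0.5)
  expect_lt(mean(tprs), 0.9)
})

test_that("AF features are invariant to amplitude scaling of the trace", {
  seg <- synth_segment("af", seed = 101)
  scaled <- seg
  scaled$samples[[1]] <- 2.5 * seg$samples[[1]]
  expect_equal(af_features(seg)[, 3:5], af_features(scaled)[, 3:5],
               tolerance = 1e-9)
})

test_that("segments with too few beats are flagged, not dropped", {
  # a 'recording' with only 4 widely spaced beats
  rec <- synth_ecg("nsr", hr_bpm = 30, seed = 51)$record
  segs <- preprocess_ecg(rec)
  f <- af_features(segs)
  expect_false(f$usable[1])
  expect_true(all(is.na(f$rmssd_n[!f$usable])))
  expect_equal(nrow(f), nrow(segs))
})
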