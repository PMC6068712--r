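test_that("phase-plot embedding puts a ramp on the main diagonal", {
  ramp <- seq(-2.9, 2.9, length.out = 500)
  img <- phase_plot(ramp, lag = 1)
  on <- which(img == 1L, arr.ind = TRUE)
  expect_true(all(abs(on[, 1] - on[, 2]) <= 1))
  expect_gt(nrow(on), 50)
})

test_that("embedded point count and lag validation follow n - lag", {
  x <- rnorm(2400)
  expect_equal(2400 - 5, length(x[-(1:5)]))
  img <- phase_plot(x, lag = 5, connect = FALSE)
  expect_lte(sum(img), 2395)
  expect_error(phase_plot(x[1:4], lag = 5), class = "ecgkit_config")
  expect_error(phase_plot(x, lag = 0), class = "ecgkit_config")
})

test_that("white noise occupies more lag-5 cells than a 1 Hz tone", {
  t <- (0:2399) / 300
  for (seed in 1:10) {
    set.seed(seed)
    noise <- normalize_signal(rnorm(2400))
    tone <- normalize_signal(sin(2 * pi * 1 * t + runif(1, 0, 2 * pi)))
    expect_gt(sum(phase_plot(noise, 5, connect = FALSE)),
              sum(phase_plot(tone, 5, connect = FALSE)))
  }
})

test_that("self-similarity index equals the pixel-ratio difference", {
  full <- matrix(1L, 50, 50)
  empty <- matrix(0L, 50, 50)
  fake <- function(m, lag) structure(m, lag = lag)
  expect_equal(self_similarity(fake(full, 1), fake(full, 5)), 0)
  expect_equal(self_similarity(fake(empty, 1), fake(full, 5)), 1)
  set.seed(7)
  for (i in 1:20) {
    b1 <- random_mask(100, runif(1, 0.05, 0.6))
    b2 <- random_mask(100, runif(1, 0.05, 0.6))
    manual <- sum(b2 == 1) / length(b2) - sum(b1 == 1) / length(b1)
    expect_equal(self_similarity(fake(b1, 1), fake(b2, 5)), manual,
                 tolerance = 1e-12)
  }
  expect_error(self_similarity(fake(full, 1), fake(matrix(1L, 40, 40), 5)),
               class = "ecgkit_config")
  expect_error(self_similarity(fake(full, 5), fake(full, 1)),
               class = "ecgkit_config")
})

test_that("diagonal-line detection matches the per-diagonal scan oracle", {
  # single 25-pixel diagonal run
  m <- matrix(0L, 100, 100)
  m[cbind(10:34, 20:44)] <- 1L
  expect_equal(diagonal_lines(m, 20), list(count = 1L, pixels = 25L))
  # exactly 20 pixels: strict threshold excludes it
  m2 <- matrix(0L, 100, 100)
  m2[cbind(10:29, 20:39)] <- 1L
  expect_equal(diagonal_lines(m2, 20), list(count = 0L, pixels = 0L))

  set.seed(11)
  for (i in 1:100) {
    m <- random_mask(60, runif(1, 0.2, 0.7))
    for (min_len in c(2L, 5L)) {
      got <- diagonal_lines(m, min_len)
      want <- oracle_diagonal_lines(m, min_len)
      expect_identical(got$count, want$count)
      expect_identical(got$pixels, want$pixels)
    }
  }
})

test_that("image subtraction clamps to binary and matches the per-pixel oracle", {
  b <- random_mask(30, 0.4)
  expect_true(all(subtract_images(b, b) == 0L))
  empty <- matrix(0L, 30, 30)
  expect_true(all(subtract_images(b, empty) == b))
  set.seed(13)
  for (i in 1:50) {
    b1 <- random_mask(40, runif(1, 0.1, 0.8))
    b2 <- random_mask(40, runif(1, 0.1, 0.8))
    got <- subtract_images(b1, b2)
    expect_true(all(got == oracle_subtract(b1, b2)))
  }
  expect_error(subtract_images(b, matrix(0L, 10, 10)), class = "ecgkit_config")
})

test_that("hole filling matches the queue-based oracle and EBImage exactly", {
  expect_equal(fill_fraction(matrix(0L, 10, 10)), 0)
  # 3x3 ring centered in a 10x10 grid: 8 ring pixels + 1 hole -> 9 filled
  ring <- matrix(0L, 10, 10)
  ring[4:6, 4] <- 1L; ring[4:6, 6] <- 1L; ring[4, 5] <- 1L; ring[6, 5] <- 1L
  filled <- fill_holes(ring)
  expect_equal(sum(filled), 9)
  expect_equal(fill_fraction(ring), 9 / 100)

  set.seed(17)
  for (i in 1:100) {
    m <- random_mask(50, runif(1, 0.2, 0.6))
    got <- fill_holes(m)
    expect_true(all(got == oracle_fill(m)))
    expect_gte(sum(got), sum(m))  # filling only adds pixels
  }
  skip_if_not_installed("EBImage")
  for (i in 1:10) {
    m <- random_mask(60, 0.35)
    eb <- EBImage::fillHull(EBImage::Image(m))@.Data
    expect_true(all(fill_holes(m) == matrix(as.integer(eb), 60)))
  }
})

test_that("a pure sinusoid segment yields a thin, nearly unfilled image", {
  x <- normalize_signal(sin(2 * pi * 2 * (0:2399) / 300))
  f <- vf_image_features(x)
  expect_lt(f$f4, 0.05)
  expect_lt(abs(f$f1), 0.2)
})

test_that("image features are stable under an amplitude sign flip", {
  # mirror symmetry is exact up to rasterization tie-breaks at cell
  # boundaries, so the comparison is approximate
  for (seed in 1:3) {
    x <- synth_segment("vf", seed = seed)$samples[[1]]
    a <- vf_image_features(x)
    b <- vf_image_features(-x)
    expect_equal(a$f1, b$f1, tolerance = 0.05)
    if (a$f2 + b$f2 > 0) expect_lt(abs(a$f2 - b$f2) / max(a$f2, b$f2), 0.35)
    expect_equal(a$f4, b$f4, tolerance = 0.05)
  }
  # the point-occupancy image is exactly mirror-symmetric in pixel count
  x <- synth_segment("nsr", seed = 4)$samples[[1]]
  expect_equal(sum(phase_plot(x, 5, connect = FALSE)),
               sum(phase_plot(-x, 5, connect = FALSE)))
})

test_that("F1-F4 invariants hold on synthetic segments", {
  for (seed in 1:5) {
    f <- vf_image_features(synth_segment(c("nsr", "vf")[seed %% 2 + 1],
                                         seed = seed)$samples[[1]])
    expect_gte(f$f1, -1); expect_lte(f$f1, 1)
    expect_gte(f$f2, 0)
    if (f$f2 > 0) expect_gte(f$f3, 20 * f$f2)
    expect_gte(f$f4, 0); expect_lte(f$f4, 1)
  }
})
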