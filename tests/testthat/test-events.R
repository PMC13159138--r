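test_that("peak detection fixtures: height, distance, plateaus", {
  p0 <- peakParams("global", 0.5, 0, 1)
  pk <- detectPeaks(c(0, 0, 1, 0, 0), 0, p0)
  expect_equal(pk$frame, 3L)
  expect_equal(pk$amplitude, 1.0)
  expect_equal(nrow(detectPeaks(rep(0, 20), 0, p0)), 0L)
  # distance conflict: higher peak wins
  x <- c(0, 0, 1, 0, 0.6, 0, 0)
  pk2 <- detectPeaks(x, 0, peakParams("global", 0.5, 0, 4))
  expect_equal(pk2$frame, 3L)
  # plateau collapses to its first frame
  xp <- c(0, 1, 1, 1, 0)
  expect_equal(detectPeaks(xp, 0, p0)$frame, 2L)
  # noise-multiplier mode scales with sigma
  xm <- c(0, 0.25, 0, 0.45, 0)
  expect_equal(detectPeaks(xm, 0.1, peakParams("noise_multiplier", 2, 0, 1))$frame,
               c(2L, 4L))
  expect_equal(detectPeaks(xm, 0.1, peakParams("noise_multiplier", 3, 0, 1))$frame,
               4L)
})

test_that("detector agrees with the exhaustive reference on random traces", {
  set.seed(21)
  for (i in 1:500) {
    T <- sample(20:300, 1)
    x <- round(cumsum(rnorm(T)) / 5 + rnorm(T), 1)  # rough, with ties
    sigma <- runif(1, 0.1, 2)
    kh <- runif(1, 0.5, 3); kp <- runif(1, 0, 2)
    d <- sample(1:8, 1)
    par <- peakParams("noise_multiplier", kh, kp, d)
    got <- detectPeaks(x, sigma, par)$frame
    want <- brute_peaks(x, kh * sigma, kp * sigma, d)
    expect_identical(got, as.integer(want))
  }
})

test_that("raising the effective height never adds peaks", {
  set.seed(22)
  for (i in 1:40) {
    x <- abs(rnorm(200, sd = 2)) * rbinom(200, 1, 0.2)
    counts <- vapply(c(0.5, 1, 2, 3, 4), function(h)
      nrow(detectPeaks(x, 1, peakParams("global", h, 0, 2))), 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("single-ROI features follow their definitions", {
  f <- computeFeatures(c(11, 21, 41), c(1, 2, 3), roi_area_px = 20,
                       T = 300, frame_rate_hz = 10, pixel_size_um = 0.5)
  expect_equal(f$event_frequency_hz, 0.1)      # 3 events in 30 s
  expect_equal(f$mean_iei_s, 1.5)              # IEIs 1.0 and 2.0 s
  expect_equal(f$amplitude_mean, 2)
  expect_equal(f$cell_size_um2, 5)             # 20 px * 0.25 um^2
  expect_true(f$active)
  f0 <- computeFeatures(integer(), numeric(), 10, 300, 10)
  expect_equal(f0$event_frequency_hz, 0)
  expect_true(is.na(f0$mean_iei_s))
  expect_false(f0$active)
})

test_that("percent active counts ROIs with at least one event", {
  expect_equal(percentActive(c(rep(TRUE, 4), rep(FALSE, 4))), 50)
  expect_equal(percentActive(rep(FALSE, 3)), 0)
  expect_equal(percentActive(c(TRUE, FALSE, FALSE)), 100 / 3)
  expect_message(expect_true(is.na(percentActive(logical()))), "no ROIs")
})
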